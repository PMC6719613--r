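# Undecimated (stationary) single-level 3-D wavelet filter bank.
#
# The low-pass (L) and high-pass (H) analysis filters of the coiflet-1 basis
# (6 taps) are applied consecutively along the three array axes without
# down-sampling, so every sub-band stays on the original voxel grid and the
# tumor mask applies unchanged. The eight L/H combinations plus the untouched
# original give nine aligned images per input volume.

# coiflet-1 analysis filters (6 taps, full double precision)
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578,    0.8525720202116004,
              0.3378976624574818,   -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645,  0.3378976624574818,
              -0.8525720202116004,  0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

#' Sub-band labels of the 3-D wavelet bank
#'
#' First letter = filter along the first array axis, second = second axis,
#' third = third axis. `ORIG` is the unfiltered input.
#' @export
SUBBAND_LABELS <- c("ORIG", "LLL", "LLH", "LHL", "LHH",
                    "HLL", "HLH", "HHL", "HHH")

# Half-sample symmetric (mirror) index fold: maps any integer position to
# 1..n, extending x as ... x2 x1 | x1 x2 ... xn | xn x(n-1) ...
reflect_index <- function(p, n) {
  q <- ((p - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  ifelse(q < n, q + 1L, 2L * n - q)
}

# Correlate a filter along one axis of a 3-D array with mirror extension;
# the window for output position i spans extended positions
# i - center + 1 .. i - center + length(f). For the 6-tap wavelet filters
# the center sits at tap 3. Same-size output.
filter_axis <- function(a, f, axis, center = 3L) {
  dm <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- prod(dim(ap)[-1])
  dim(ap) <- c(n, m)
  out <- matrix(0, n, m)
  idx <- seq_len(n)
  for (t in seq_along(f)) {
    rows <- reflect_index(idx + t - center, n)
    out <- out + f[t] * ap[rows, , drop = FALSE]
  }
  dim(out) <- dm[perm]
  aperm(out, order(perm))
}

#' Decompose a volume into the 9-image wavelet bank
#'
#' Applies the coiflet-1 low/high-pass pair along each of the three axes of
#' space in turn, without down-sampling (stationary transform, one level),
#' producing the eight sub-bands LLL..HHH aligned with the input grid, plus
#' the original image. Boundaries are handled by half-sample mirror
#' extension, which also accommodates dimensions shorter than the 6-tap
#' filter.
#'
#' @param volume An [image_volume()] (or bare 3-D array).
#' @return A `wavelet_bank`: named list of nine 3-D arrays
#'   (see [SUBBAND_LABELS]), all with the input's shape; `ORIG` is the input
#'   itself.
#' @export
decompose <- function(volume) {
  a <- if (inherits(volume, "image_volume")) volume$data else as.array(volume)
  if (length(dim(a)) != 3L)
    stop("decompose: input must be a 3-D volume")
  lo <- COIF1_LO; hi <- COIF1_HI
  ax1 <- list(L = filter_axis(a, lo, 1), H = filter_axis(a, hi, 1))
  ax2 <- list()
  for (l1 in names(ax1)) {
    ax2[[paste0(l1, "L")]] <- filter_axis(ax1[[l1]], lo, 2)
    ax2[[paste0(l1, "H")]] <- filter_axis(ax1[[l1]], hi, 2)
  }
  bank <- list(ORIG = a)
  for (l12 in names(ax2)) {
    bank[[paste0(l12, "L")]] <- filter_axis(ax2[[l12]], lo, 3)
    bank[[paste0(l12, "H")]] <- filter_axis(ax2[[l12]], hi, 3)
  }
  bank <- bank[SUBBAND_LABELS]
  class(bank) <- "wavelet_bank"
  bank
}

#' Export a wavelet bank as NIfTI files
#'
#' Debug helper: writes each sub-band next to the source volume with the
#' sub-band label as suffix (e.g. `tumor_LLL.nii.gz`).
#'
#' @param bank A `wavelet_bank` from [decompose()].
#' @param stem Output path stem (without extension).
#' @param spacing Voxel spacing to record in the headers.
#' @return Character vector of written paths, invisibly.
#' @export
export_bank <- function(bank, stem, spacing = c(1, 1, 1)) {
  paths <- character(0)
  for (lab in setdiff(names(bank), "ORIG")) {
    p <- paste0(stem, "_", lab, ".nii.gz")
    write_volume(image_volume(bank[[lab]], spacing, id = lab), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
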