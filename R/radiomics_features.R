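# Texture matrices and the radiomic feature catalog.
#
# All matrix features follow the IBSI formulations on a quantized ROI with
# levels 1..G. Zones are connected components of equal-level voxels
# (26-connectivity by default); runs are maximal collinear equal-level
# sequences aggregated over the 13 unique 3-D directions ("merged"
# convention); co-occurrences are distance-1 pairs over the same 13
# directions, symmetrized.

#' Enumerate gray-level zones
#'
#' A zone is a connected component, under the given connectivity, of ROI
#' voxels sharing one gray level. Every ROI voxel belongs to exactly one
#' zone.
#'
#' @param disc A `discretized_roi` from [discretize()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return Integer matrix with columns `level` and `size`, one row per zone.
#' @export
label_zones <- function(disc, connectivity = 26) {
  stopifnot(inherits(disc, "discretized_roi"))
  cpp_label_zones(as.integer(disc$levels), as.integer(dim(disc$levels)),
                  as.integer(connectivity))
}

#' Build the gray-level size-zone matrix (GLSZM)
#'
#' `counts[i, j]` is the number of zones of gray level `i` and size `j`.
#' A homogeneous ROI concentrates mass at large `j`; heterogeneous ROIs
#' fragment into many small zones.
#'
#' @inheritParams label_zones
#' @return A `glszm`: list with `counts` (G x Jmax), `n_zones`, `n_voxels`.
#' @export
build_glszm <- function(disc, connectivity = 26) {
  zones <- label_zones(disc, connectivity)
  G <- disc$n_levels
  jmax <- max(zones[, "size"])
  cell <- (zones[, "size"] - 1L) * G + zones[, "level"]
  counts <- matrix(tabulate(cell, G * jmax), G, jmax)
  structure(list(counts = counts, n_zones = nrow(zones),
                 n_voxels = sum(disc$levels > 0)),
            class = "glszm")
}

#' Build the gray-level run-length matrix (GLRLM)
#'
#' `counts[i, j]` is the number of maximal runs of gray level `i` and length
#' `j`, summed over the 13 unique 3-D directions.
#'
#' @param disc A `discretized_roi`.
#' @return A `glrlm`: list with `counts`, `n_runs`, `n_voxels`.
#' @export
build_glrlm <- function(disc) {
  stopifnot(inherits(disc, "discretized_roi"))
  counts <- cpp_glrlm(as.integer(disc$levels), as.integer(dim(disc$levels)),
                      disc$n_levels)
  structure(list(counts = counts, n_runs = sum(counts),
                 n_voxels = sum(disc$levels > 0)),
            class = "glrlm")
}

#' Build the gray-level co-occurrence matrix (GLCM)
#'
#' Symmetric distance-1 co-occurrence counts aggregated over the 13 unique
#' 3-D directions, with normalized probabilities.
#'
#' @param disc A `discretized_roi`.
#' @return A `glcm`: list with `counts` and `p` (probabilities summing to 1).
#' @export
build_glcm <- function(disc) {
  stopifnot(inherits(disc, "discretized_roi"))
  counts <- cpp_glcm(as.integer(disc$levels), as.integer(dim(disc$levels)),
                     disc$n_levels)
  tot <- sum(counts)
  structure(list(counts = counts, p = if (tot > 0) counts / tot else counts),
            class = "glcm")
}

szm_weights <- function(counts) {
  i <- row(counts); j <- col(counts)
  list(i = i, j = j)
}

#' Small zone emphasis
#'
#' `SZE = (1/N_s) * sum_ij s(i,j) / j^2`, in (0, 1]. Lower values indicate a
#' more heterogeneous intensity distribution (many small zones).
#'
#' @param m A `glszm`.
#' @return Scalar feature value.
#' @export
sze <- function(m) {
  stopifnot(inherits(m, "glszm"))
  if (m$n_zones < 1) stop("sze: empty GLSZM")
  w <- szm_weights(m$counts)
  sum(m$counts / w$j^2) / m$n_zones
}

#' Small zone low gray-level emphasis
#'
#' `SZLGE = (1/N_s) * sum_ij s(i,j) / (i^2 * j^2)`, in (0, 1].
#'
#' @param m A `glszm`.
#' @return Scalar feature value.
#' @export
szlge <- function(m) {
  stopifnot(inherits(m, "glszm"))
  if (m$n_zones < 1) stop("szlge: empty GLSZM")
  w <- szm_weights(m$counts)
  sum(m$counts / (w$i^2 * w$j^2)) / m$n_zones
}

#' High gray-level run emphasis
#'
#' `HGRE = (1/N_r) * sum_ij i^2 * r(i,j)`, >= 1.
#'
#' @param m A `glrlm`.
#' @return Scalar feature value.
#' @export
hgre <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  if (m$n_runs < 1) stop("hgre: empty GLRLM")
  w <- szm_weights(m$counts)
  sum(m$counts * w$i^2) / m$n_runs
}

# Full GLSZM catalog (11 features).
glszm_features <- function(m) {
  s <- m$counts; Ns <- m$n_zones; Nv <- m$n_voxels
  i <- row(s); j <- col(s)
  c(GLSZM_SZE   = sum(s / j^2) / Ns,
    GLSZM_LZE   = sum(s * j^2) / Ns,
    GLSZM_LGZE  = sum(s / i^2) / Ns,
    GLSZM_HGZE  = sum(s * i^2) / Ns,
    GLSZM_SZLGE = sum(s / (i^2 * j^2)) / Ns,
    GLSZM_SZHGE = sum(s * i^2 / j^2) / Ns,
    GLSZM_LZLGE = sum(s * j^2 / i^2) / Ns,
    GLSZM_LZHGE = sum(s * i^2 * j^2) / Ns,
    GLSZM_GLN   = sum(rowSums(s)^2) / Ns,
    GLSZM_ZSN   = sum(colSums(s)^2) / Ns,
    GLSZM_ZP    = Ns / Nv)
}

# Full GLRLM catalog (11 features). RP is normalized per direction
# (13 scans of Nv voxels each under the merged convention).
glrlm_features <- function(m) {
  r <- m$counts; Nr <- m$n_runs; Nv <- m$n_voxels
  i <- row(r); j <- col(r)
  c(GLRLM_SRE   = sum(r / j^2) / Nr,
    GLRLM_LRE   = sum(r * j^2) / Nr,
    GLRLM_LGRE  = sum(r / i^2) / Nr,
    GLRLM_HGRE  = sum(r * i^2) / Nr,
    GLRLM_SRLGE = sum(r / (i^2 * j^2)) / Nr,
    GLRLM_SRHGE = sum(r * i^2 / j^2) / Nr,
    GLRLM_LRLGE = sum(r * j^2 / i^2) / Nr,
    GLRLM_LRHGE = sum(r * i^2 * j^2) / Nr,
    GLRLM_GLN   = sum(rowSums(r)^2) / Nr,
    GLRLM_RLN   = sum(colSums(r)^2) / Nr,
    GLRLM_RP    = Nr / (13 * Nv))
}

# GLCM catalog (6 features). Correlation is undefined (missing) when the
# marginal variance vanishes (single effective gray level).
glcm_features <- function(m) {
  p <- m$p
  i <- row(p); j <- col(p)
  pi_ <- rowSums(p)
  mu_i <- sum(seq_along(pi_) * pi_)
  var_i <- sum((seq_along(pi_) - mu_i)^2 * pi_)
  corr <- if (var_i > 0)
    sum((i - mu_i) * (j - mu_i) * p) / var_i
  else NA_real_
  pos <- p > 0
  c(GLCM_energy        = sum(p^2),
    GLCM_contrast      = sum((i - j)^2 * p),
    GLCM_dissimilarity = sum(abs(i - j) * p),
    GLCM_homogeneity   = sum(p / (1 + abs(i - j))),
    GLCM_entropy       = -sum(p[pos] * log2(p[pos])),
    GLCM_correlation   = corr)
}

#' First-order intensity features
#'
#' Moments and order statistics of the ROI intensity distribution; entropy
#' and uniformity are computed on a fixed-bin-number histogram of the
#' values. Variance is the population variance; skewness and kurtosis are
#' the standardized third and fourth moments (missing for a constant ROI).
#'
#' @param values Numeric vector of ROI intensities.
#' @param n_bins Histogram bins for entropy/uniformity (default 64).
#' @return Named numeric vector.
#' @export
first_order_features <- function(values, n_bins = 64) {
  stopifnot(length(values) >= 1)
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  skew <- if (m2 > 0) mean((values - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((values - mu)^4) / m2^2 else NA_real_
  rng <- max(values) - min(values)
  if (rng > 0) {
    lev <- pmin(n_bins, floor(n_bins * (values - min(values)) / rng) + 1L)
  } else lev <- rep.int(1L, n)
  pr <- tabulate(lev, n_bins) / n
  pr <- pr[pr > 0]
  c(FO_mean = mu,
    FO_variance = m2,
    FO_skewness = skew,
    FO_kurtosis = kurt,
    FO_median = median(values),
    FO_min = min(values),
    FO_max = max(values),
    FO_p10 = unname(quantile(values, 0.10, type = 7)),
    FO_p90 = unname(quantile(values, 0.90, type = 7)),
    FO_energy = sum(values^2),
    FO_entropy = -sum(pr * log2(pr)),
    FO_uniformity = sum(pr^2))
}

#' Shape features of a tumor mask
#'
#' Voxel-count volume, face-adjacency surface area, sphericity and maximum
#' 3-D diameter (largest center-to-center distance between boundary
#' voxels), all in mm using the voxel spacing.
#'
#' @param mask An [roi_mask()].
#' @param spacing Voxel spacing triple in mm.
#' @return Named numeric vector.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$data
  dm <- dim(m)
  nv <- sum(m)
  vol <- nv * prod(spacing)

  # exposed-face surface area: voxel faces not shared with another ROI voxel
  pad <- array(FALSE, dm + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  area <- 0
  exposed_any <- array(FALSE, dm)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[2:(dm[1] + 1) + s[1], 2:(dm[2] + 1) + s[2],
              2:(dm[3] + 1) + s[3], drop = FALSE]
    dim(nb) <- dm
    exposed <- m & !nb
    area <- area + sum(exposed) * face_area[which(s != 0)]
    exposed_any <- exposed_any | exposed
  }

  # max diameter over boundary voxel centers
  idx <- which(exposed_any, arr.ind = TRUE)
  xyz <- sweep(idx - 1, 2, spacing, `*`)
  maxd <- if (nrow(xyz) == 1) 0 else max(stats::dist(xyz))
  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area
  c(SHAPE_volume_mm3 = vol,
    SHAPE_surface_mm2 = area,
    SHAPE_sphericity = sphericity,
    SHAPE_max_diameter_mm = maxd)
}

#' Default discretization scheme grid
#'
#' Fixed-bin-number schemes with G in `bins`; the grid stands in for the
#' unavailable per-feature parametrization settings and is fully
#' configurable.
#'
#' @param bins Integer vector of bin counts.
#' @return List of [discretization_scheme()] objects.
#' @export
default_scheme_grid <- function(bins = c(8, 16, 32, 64)) {
  lapply(bins, function(g) discretization_scheme("fixed-bin-number", g))
}

#' Extract the full feature-variant row for one patient
#'
#' For each sequence's wavelet bank, computes shape features once (keyed
#' under the ORIG sub-band), first-order features per sub-band, and the
#' GLSZM/GLRLM/GLCM catalogs per (sub-band, discretization scheme). Keys
#' follow `"SEQ|SUBBAND|SCHEME|FEATURE"` (e.g. `"ADC|LLL|FBN32|GLSZM_SZE"`)
#' in a deterministic order. Features undefined on degenerate ROIs are
#' emitted as `NA`, never coerced to 0.
#'
#' @param banks Named list (sequence name -> `wavelet_bank`).
#' @param mask An [roi_mask()] shared by all sub-bands of each sequence.
#' @param schemes List of [discretization_scheme()]s
#'   (default [default_scheme_grid()]).
#' @param connectivity Zone connectivity, 6 or 26.
#' @param spacing Named list (sequence -> spacing triple); defaults to unit
#'   spacing.
#' @return Named numeric vector, one value per feature-variant key.
#' @export
extract_all <- function(banks, mask, schemes = default_scheme_grid(),
                        connectivity = 26, spacing = NULL) {
  # texture matrices are invariant to cropping away pure-background slabs;
  # restrict to the mask bounding box to avoid scanning empty voxels
  bb <- lapply(1:3, function(ax) {
    pres <- apply(mask$data, ax, any)
    range(which(pres))
  })
  crop <- function(a) a[bb[[1]][1]:bb[[1]][2], bb[[2]][1]:bb[[2]][2],
                        bb[[3]][1]:bb[[3]][2], drop = FALSE]
  mask_c <- roi_mask(crop(mask$data))
  out <- list()
  for (seq_name in sort(names(banks))) {
    bank <- banks[[seq_name]]
    sp <- if (!is.null(spacing) && seq_name %in% names(spacing))
      spacing[[seq_name]] else c(1, 1, 1)
    sh <- shape_features(mask_c, sp)
    names(sh) <- sprintf("%s|ORIG|SHAPE|%s", seq_name, names(sh))
    out[[length(out) + 1]] <- sh
    for (sb in SUBBAND_LABELS) {
      vol <- image_volume(crop(bank[[sb]]), sp,
                          id = paste(seq_name, sb, sep = "_"))
      fo <- first_order_features(masked_intensities(vol, mask_c))
      names(fo) <- sprintf("%s|%s|FO|%s", seq_name, sb, names(fo))
      out[[length(out) + 1]] <- fo
      for (sc in schemes) {
        disc <- discretize(vol, mask_c, sc)
        fx <- c(glszm_features(build_glszm(disc, connectivity)),
                glrlm_features(build_glrlm(disc)),
                glcm_features(build_glcm(disc)))
        names(fx) <- sprintf("%s|%s|%s|%s", seq_name, sb, sc$label, names(fx))
        out[[length(out) + 1]] <- fx
      }
    }
  }
  row <- unlist(out)
  row[order(names(row))]
}

#' Base feature of a feature-variant key
#'
#' Variants of one base feature differ in sub-band and discretization but
#' share sequence and feature name; selection retains at most one variant
#' per base feature.
#'
#' @param keys Character vector of `"SEQ|SUBBAND|SCHEME|FEATURE"` keys.
#' @return Character vector of `"SEQ|FEATURE"` base keys.
#' @export
variant_base <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  vapply(parts, function(p) paste(p[1], p[4], sep = "|"), character(1))
}
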