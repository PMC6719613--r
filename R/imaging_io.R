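#' @useDynLib bcradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median quantile rnorm runif rbinom sd var setNames
#'   pchisq pnorm qnorm rexp uniroot complete.cases wilcox.test
#' @importFrom utils head write.csv read.csv
NULL

#' Construct a 3-D image volume
#'
#' An `image_volume` couples a 3-D scalar intensity array with its voxel
#' spacing (mm) and an identifier tag (typically patient/sequence).
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing Numeric triple of voxel dimensions in mm, all > 0.
#' @param id Identifier string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), id = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: data must be a 3-D array, got ",
         length(dim(data)), " dimensions")
  if (anyNA(data))
    stop("image_volume: data contains NaN/NA voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be three positive values")
  structure(list(data = data, spacing = spacing, id = as.character(id)),
            class = "image_volume")
}

#' Construct a binary ROI mask
#'
#' @param data 3-D array coercible to 0/1; any non-zero voxel is foreground.
#' @return An object of class `roi_mask` whose `data` is a logical array.
#' @export
roi_mask <- function(data) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("roi_mask: data must be a 3-D array")
  m <- data != 0
  if (anyNA(m)) stop("roi_mask: mask contains NA voxels")
  if (!any(m)) stop("roi_mask: mask has no foreground voxels")
  structure(list(data = m), class = "roi_mask")
}

#' Load a 3-D volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file, taking voxel spacing from the header.
#' Volumes with non-3-D data or NaN voxels are rejected; texture statistics
#' must never be computed over silently imputed values.
#'
#' @param path Path to a readable NIfTI file containing 3-D data.
#' @param id Identifier; defaults to the file name without extension.
#' @return An [image_volume()].
#' @export
load_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("load_volume: cannot read '", path, "'")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("load_volume: failed to read '",
                                           path, "': ", conditionMessage(e)))
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("load_volume: '", path, "' has ", length(dm),
         "-D data; a 3-D volume is required")
  if (anyNA(img))
    stop("load_volume: '", path, "' contains NaN voxels")
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  image_volume(array(as.numeric(img), dim = dm),
               spacing = RNifti::pixdim(img)[1:3], id = id)
}

#' Load a binary ROI mask from a NIfTI file
#'
#' @param path Path to a NIfTI mask (0 = background, non-zero = tumor).
#' @return An [roi_mask()].
#' @export
load_mask <- function(path) {
  vol <- load_volume(path)
  roi_mask(vol$data)
}

#' Write a volume to a NIfTI file
#'
#' @param volume An [image_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_geometry <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask shapes differ: ",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(mask$data), collapse = "x"))
}

#' Extract ROI intensities in scan order
#'
#' Returns intensities at foreground voxels in column-major (first axis
#' fastest) scan order, the array storage order.
#'
#' @param volume An [image_volume()].
#' @param mask An [roi_mask()] with the same shape.
#' @return Numeric vector of ROI intensities.
#' @export
masked_intensities <- function(volume, mask) {
  check_geometry(volume, mask)
  volume$data[mask$data]
}

#' Gray-level discretization scheme
#'
#' Two conventions are supported for quantizing ROI intensities before
#' texture-matrix construction:
#' \describe{
#'   \item{fixed-bin-number (FBN)}{`G` equal-width bins over the ROI range;
#'     level = `min(G, floor(G * (x - min) / (max - min)) + 1)`; a constant
#'     ROI maps entirely to level 1.}
#'   \item{fixed-bin-size (FBS)}{bins of width `w` anchored at the ROI
#'     minimum; level = `floor((x - min) / w) + 1`.}
#' }
#' ROI minimum and maximum are computed on masked voxels only.
#'
#' @param method `"fixed-bin-number"` or `"fixed-bin-size"`.
#' @param parameter Integer bin count (>= 2) for FBN, positive bin width for
#'   FBS.
#' @return An object of class `discretization_scheme` with a compact `label`
#'   (e.g. `"FBN32"`) used in feature-variant keys.
#' @export
discretization_scheme <- function(method = c("fixed-bin-number",
                                             "fixed-bin-size"),
                                  parameter) {
  method <- match.arg(method)
  parameter <- as.numeric(parameter)
  if (method == "fixed-bin-number") {
    if (parameter < 2 || parameter != round(parameter))
      stop("fixed-bin-number requires an integer bin count >= 2")
    label <- sprintf("FBN%d", as.integer(parameter))
  } else {
    if (!is.finite(parameter) || parameter <= 0)
      stop("fixed-bin-size requires a positive bin width")
    label <- sprintf("FBS%g", parameter)
  }
  structure(list(method = method, parameter = parameter, label = label),
            class = "discretization_scheme")
}

#' Discretize ROI intensities to integer gray levels
#'
#' Produces the quantized image used by all texture matrices: background
#' voxels are 0, ROI voxels carry levels `1..G`. Discretization is monotone
#' in intensity. A constant ROI under fixed-bin-number is not an error: all
#' voxels map to level 1.
#'
#' @param volume An [image_volume()].
#' @param mask An [roi_mask()] of identical shape.
#' @param scheme A [discretization_scheme()].
#' @return A `discretized_roi`: list with `levels` (3-D integer array),
#'   `n_levels` (G, the nominal level count), and `scheme`.
#' @export
discretize <- function(volume, mask, scheme) {
  check_geometry(volume, mask)
  stopifnot(inherits(scheme, "discretization_scheme"))
  x <- volume$data[mask$data]
  lo <- min(x); hi <- max(x)
  if (scheme$method == "fixed-bin-number") {
    G <- as.integer(scheme$parameter)
    if (hi == lo) {
      lev <- rep.int(1L, length(x))
      G_nom <- G
    } else {
      lev <- pmin(G, floor(G * (x - lo) / (hi - lo)) + 1L)
      G_nom <- G
    }
  } else {
    w <- scheme$parameter
    lev <- floor((x - lo) / w) + 1L
    G_nom <- max(lev)
  }
  levels <- array(0L, dim = dim(volume$data))
  levels[mask$data] <- as.integer(lev)
  structure(list(levels = levels, n_levels = as.integer(G_nom),
                 scheme = scheme),
            class = "discretized_roi")
}
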