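#' @useDynLib lazone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Tissue label codes used throughout the package
#'
#' Integer codes for the label volumes the pipeline consumes: background,
#' lateral ventricles, white matter by lobe, and cortical gray matter.
#' White matter carries four codes (one per lobe) so that the
#' anterior/posterior partition can be read straight off the labels.
#'
#' @format Named integer vector.
#' @export
LABELS <- c(
  background   = 0L,
  ventricle    = 1L,
  wm_frontal   = 2L,
  wm_parietal  = 3L,
  wm_occipital = 4L,
  wm_temporal  = 5L,
  cortex       = 6L
)

#' White matter label codes (all four lobes)
#' @export
WM_LABELS <- unname(LABELS[c("wm_frontal", "wm_parietal", "wm_occipital",
                             "wm_temporal")])

#' Construct a 3-D volume with physical voxel spacing
#'
#' Lightweight container pairing a 3-D array with its voxel spacing in mm.
#' All pipeline stages operate on `vol3d` objects and enforce grid equality
#' (same dimensions and spacing) between co-registered inputs; nothing in
#' the package resamples.
#'
#' @param data 3-D array (numeric, integer, or logical).
#' @param spacing Numeric length-3, mm per voxel along each axis; strictly
#'   positive and finite.
#' @return A `vol3d` object.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("vol3d requires a 3-D array, got ", length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  structure(list(data = data, spacing = spacing), class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("vol3d: %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              typeof(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' Voxel volume in cubic millimetres
#' @param x A `vol3d`.
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Test whether two volumes share a grid
#'
#' @param a,b `vol3d` objects.
#' @param tol Relative tolerance on spacing comparison.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(a$spacing, b$spacing))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (dims ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ", spacing ",
         paste(a$spacing, collapse = "x"), " vs ",
         paste(b$spacing, collapse = "x"), "); inputs must be co-registered")
  invisible(TRUE)
}

#' Squared Euclidean distance transform, spacing-aware
#'
#' For every voxel, the squared distance in mm^2 to the nearest `TRUE`
#' voxel of `mask`, with per-axis physical spacing. Exact (separable
#' Felzenszwalb-Huttenlocher lower-envelope algorithm); voxels of an empty
#' mask are at infinite distance.
#'
#' @param mask `vol3d` with logical data.
#' @return `vol3d` of squared mm distances.
#' @export
edt_squared <- function(mask) {
  stopifnot(inherits(mask, "vol3d"))
  d <- .edt_squared_cpp(as.logical(mask$data), dim(mask$data), mask$spacing)
  vol3d(array(d, dim(mask$data)), mask$spacing)
}

#' Label connected components (26-connectivity)
#'
#' @param mask `vol3d` with logical data.
#' @return `vol3d` of integer component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "vol3d"))
  l <- .label_components_cpp(as.logical(mask$data), dim(mask$data))
  vol3d(array(l, dim(mask$data)), mask$spacing)
}

#' Read a 3-D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `vol3d` carrying the voxel data and pixel spacing.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), "-D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-finite or non-positive voxel spacing in ", path)
  vol3d(array(as.vector(img), d), sp)
}

#' Write a volume to NIfTI
#'
#' @param vol A `vol3d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype; `"auto"` picks uint8 for logical,
#'   int32 for integer, float64 otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  stopifnot(inherits(vol, "vol3d"))
  dat <- vol$data
  if (datatype == "auto")
    datatype <- if (is.logical(dat)) "uint8"
                else if (is.integer(dat)) "int32" else "double"
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  RNifti::pixdim(dat) <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(dat, datatype = datatype), path)
  invisible(path)
}

as_mask <- function(vol) {
  vol3d(array(as.logical(vol$data), dim(vol$data)), vol$spacing)
}
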