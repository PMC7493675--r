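# Threshold-based leukoaraiosis segmentation on FLAIR-like volumes:
# per-axial-slice thresholding against reference-tissue statistics,
# stacked into a 3-D mask, with optional pre-smoothing and small-component
# filtering, plus Dice mask agreement.

#' Segmentation parameters
#'
#' The threshold is `location + k * scale` of the intensity distribution in
#' the reference tissue (white matter by default). With `robust = TRUE`
#' (the default) location/scale are median and 1.4826*MAD, which are
#' insensitive to the lesion voxels that contaminate the reference region;
#' `robust = FALSE` uses the classical mean and SD. In `"slice"` mode each
#' axial slice is thresholded against its own reference statistics and the
#' 2-D masks are stacked; `"global"` uses one volume-wide threshold.
#'
#' @param reference_labels Label codes defining normal reference tissue.
#' @param k Threshold multiplier (finite).
#' @param min_component_voxels Connected components (26-connectivity)
#'   smaller than this are removed; 0 disables the filter.
#' @param mode `"slice"` (per-axial-slice thresholds) or `"global"`.
#' @param robust Use median/MAD location-scale (default) or mean/SD.
#' @param smooth_sigma_mm Gaussian pre-smoothing SD in mm (0 = off);
#'   suppresses voxel noise before thresholding.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(reference_labels = WM_LABELS, k = 3,
                                min_component_voxels = 0L,
                                mode = c("slice", "global"),
                                robust = TRUE, smooth_sigma_mm = 0) {
  if (!is.finite(k)) stop("k must be finite")
  if (min_component_voxels < 0) stop("min_component_voxels must be >= 0")
  structure(list(reference_labels = as.integer(reference_labels), k = k,
                 min_component_voxels = as.integer(min_component_voxels),
                 mode = match.arg(mode), robust = isTRUE(robust),
                 smooth_sigma_mm = smooth_sigma_mm),
            class = "segmentation_params")
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

conv1_reflect <- function(v, k) {
  r <- (length(k) - 1L) / 2L
  n <- length(v)
  pad <- c(v[pmin(n, pmax(1, r:1))], v, v[pmin(n, pmax(1, n - (1:r) + 1))])
  out <- stats::filter(pad, k, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

smooth_gaussian <- function(vol, sigma_mm) {
  arr <- vol$data
  for (ax in 1:3) {
    sig <- sigma_mm / vol$spacing[ax]
    if (sig <= 0) next
    k <- gauss_kernel(sig)
    arr <- apply(arr, setdiff(1:3, ax), conv1_reflect, k = k)
    # apply() returns the convolved axis first; restore the original order
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  vol3d(arr, vol$spacing)
}

loc_scale <- function(v, robust) {
  if (robust) c(stats::median(v), stats::mad(v))
  else c(mean(v), stats::sd(v))
}

#' Segment leukoaraiosis by intensity thresholding
#'
#' Voxels of the reference tissue whose intensity strictly exceeds the
#' slice (or global) threshold are marked as lesion; the per-slice binary
#' masks are stacked into a 3-D mask and components smaller than
#' `min_component_voxels` are removed. A slice with an empty reference
#' region falls back to the global threshold (with a message).
#'
#' @param intensity Numeric `vol3d` (FLAIR-like).
#' @param labels Label `vol3d` on the same grid.
#' @param params A [segmentation_params()].
#' @return Logical `vol3d` lesion mask (subset of the reference tissue).
#' @export
segment_la <- function(intensity, labels, params = segmentation_params()) {
  stopifnot(inherits(intensity, "vol3d"), inherits(labels, "vol3d"))
  stop_if_grid_mismatch(intensity, labels, "intensity and label volumes")
  img <- if (params$smooth_sigma_mm > 0)
    smooth_gaussian(intensity, params$smooth_sigma_mm) else intensity
  ref <- array(labels$data %in% params$reference_labels, dim(labels$data))
  if (!any(ref)) stop("reference region is empty in the label volume")
  gl <- loc_scale(img$data[ref], params$robust)
  thr_global <- gl[1] + params$k * gl[2]
  mask <- array(FALSE, dim(img$data))
  if (params$mode == "global") {
    mask <- ref & img$data > thr_global
  } else {
    # two-pass: a global pre-pass flags candidate lesions so that slice
    # statistics come from normal-appearing reference tissue only (heavily
    # lesioned slices would otherwise contaminate their own threshold)
    candidate <- ref & img$data > thr_global
    nz <- dim(img$data)[3]
    fallback <- 0L
    for (z in seq_len(nz)) {
      rs <- ref[, , z]
      clean <- rs & !candidate[, , z]
      if (!any(clean)) { thr <- thr_global; fallback <- fallback + 1L }
      else {
        ls <- loc_scale(img$data[, , z][clean], params$robust)
        thr <- ls[1] + params$k * ls[2]
      }
      mask[, , z] <- rs & img$data[, , z] > thr
    }
    if (fallback > 0)
      message(fallback, " slice(s) had an empty reference region; ",
              "global threshold used")
  }
  out <- vol3d(mask, intensity$spacing)
  if (params$min_component_voxels > 1L && any(mask)) {
    comp <- label_components(out)
    sizes <- tabulate(comp$data[comp$data > 0L])
    keep <- which(sizes >= params$min_component_voxels)
    out <- vol3d(array(comp$data %in% keep & mask, dim(mask)),
                 intensity$spacing)
  }
  out
}

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty
#' (two empty segmentations agree perfectly).
#'
#' @param a,b Logical `vol3d` masks on the same grid.
#' @return Number in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "vol3d"), inherits(b, "vol3d"))
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}
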