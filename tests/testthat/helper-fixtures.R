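# Fixture builders and independent oracles shared across the suite.

# small phantom spec that exercises all labels on a compact grid
small_spec <- function(grid = c(24, 24, 24), spacing = c(1, 1, 1), ...) {
  phantom_spec(grid_shape = grid, spacing = spacing,
               brain_semiaxes = c(10, 11, 9),
               ribbon_thickness = 2,
               ventricle_centers = rbind(c(-3, 0, 0), c(3, 0, 0)),
               ventricle_semiaxes = rbind(c(1.5, 3, 2), c(1.5, 3, 2)),
               lobe_planes = list(frontal_y = 4, occipital_y = -5,
                                  temporal_z = -3),
               ...)
}

# hand-built label volume from index predicates
toy_labels <- function(dims, spacing = c(1, 1, 1), fill = LABELS[["background"]]) {
  vol3d(array(as.integer(fill), dims), spacing)
}

set_label <- function(vol, label, ix, iy, iz) {
  vol$data[ix, iy, iz] <- LABELS[[label]]
  vol
}

# brute-force all-pairs mm-distance band oracle: WM voxels within width_mm
# of any voxel carrying `target_label`
brute_band <- function(labels, target_label, width_mm, exclude_target = FALSE) {
  dims <- dim(labels$data)
  sp <- labels$spacing
  tgt <- which(labels$data == LABELS[[target_label]])
  out <- array(FALSE, dims)
  if (length(tgt) == 0) return(vol3d(out, sp))
  tpos <- arrayInd(tgt, dims)
  wm <- which(array(labels$data %in% WM_LABELS, dims))
  wpos <- arrayInd(wm, dims)
  for (i in seq_along(wm)) {
    d2 <- (sweep(tpos, 2, wpos[i, ]) %*% diag(sp))^2
    if (min(rowSums(d2)) <= width_mm^2) out[wm[i]] <- TRUE
  }
  if (exclude_target) out[tgt] <- FALSE
  vol3d(out, sp)
}

# textbook moment formulas, written independently of the package internals
oracle_skewness <- function(x) {
  n <- length(x)
  z <- (x - mean(x)) / sd(x)
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

mask_of <- function(labels, predicate) {
  vol3d(array(predicate(labels$data), dim(labels$data)), labels$spacing)
}
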