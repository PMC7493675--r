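# Synthetic brain phantoms: labeled geometry, planted hyperintense lesions at
# controlled depths, FLAIR-like rendering, and two-group cohort simulation.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default FLAIR-like tissue intensity means
#'
#' Arbitrary-unit means for the rendered phantom: CSF (ventricle) dark,
#' white matter mid, cortical gray slightly brighter, hyperintense lesions
#' well above white matter, lacunar cavities dark.
#' @export
default_tissue_means <- function() {
  c(background = 5, ventricle = 20,
    wm_frontal = 100, wm_parietal = 100, wm_occipital = 100, wm_temporal = 100,
    cortex = 115, lesion = 160, lacuna = 30)
}

#' Specify a brain phantom
#'
#' Parametric description of a labeled brain phantom: an ellipsoidal brain
#' with a cortical gray ribbon, two ellipsoidal lateral ventricles, and
#' axis-aligned planes splitting white matter into frontal / parietal /
#' occipital / temporal compartments. Default dimensions were chosen so the
#' three depth zones (5 mm periventricular and infracortical bands) occupy
#' volume shares of white matter under which the preset per-zone lesion
#' loads are mutually consistent with the preset total loads.
#'
#' @param grid_shape Voxel counts per axis.
#' @param spacing mm per voxel per axis.
#' @param brain_semiaxes Outer (pial) ellipsoid semi-axes, mm.
#' @param ribbon_thickness Cortical gray band thickness, mm.
#' @param ventricle_centers 2x3 matrix of ventricle center offsets from the
#'   grid center, mm.
#' @param ventricle_semiaxes 2x3 matrix of ventricle semi-axes, mm (zero
#'   rows give an empty ventricle).
#' @param lobe_planes Named list: `frontal_y` and `occipital_y` are signed
#'   mm offsets from the grid center along axis 2 (anterior = +y) cutting
#'   frontal (y >= frontal_y) and occipital (y <= occipital_y) white
#'   matter; `temporal_z` splits the middle band into parietal (above) and
#'   temporal (below), mm offset along axis 3.
#' @param zone_targets Planted lesion load per depth zone, percent of zonal
#'   white matter, named `pv`, `deep`, `ic`; each in \[0, 100\].
#' @param lacunae_plan Data frame with columns `x`, `y`, `z` (center mm
#'   offsets from grid center) and `diameter` (mm), or NULL.
#' @param stroke_plan Data frame with columns `d1`, `d2` (in-plane
#'   diameters, mm), `n_slices`, `slice_thickness`, or NULL. Strokes are
#'   radiologist-style caliper measurements; they are volumetrized by
#'   formula, not voxelized.
#' @param noise_sd Gaussian intensity noise SD, arbitrary units.
#' @param scale Global geometry scale factor (head-size variation).
#' @param seed Integer seed making every stochastic stage reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         brain_semiaxes = c(26, 29, 25),
                         ribbon_thickness = 3,
                         ventricle_centers = rbind(c(-5, 0, 1), c(5, 0, 1)),
                         ventricle_semiaxes = rbind(c(1.5, 4, 2), c(1.5, 4, 2)),
                         lobe_planes = list(frontal_y = 9, occipital_y = -15,
                                            temporal_z = -9),
                         zone_targets = c(pv = 0, deep = 0, ic = 0),
                         lacunae_plan = NULL,
                         stroke_plan = NULL,
                         noise_sd = 6,
                         scale = 1,
                         seed = 1L) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("spacing must be strictly positive and finite")
  zone_targets <- zone_targets[c("pv", "deep", "ic")]
  if (any(is.na(zone_targets)))
    stop("zone_targets must be named pv, deep, ic")
  if (any(zone_targets < 0 | zone_targets > 100))
    stop("zone_targets must lie in [0, 100] percent")
  if (!is.null(lacunae_plan) && nrow(lacunae_plan) > 0) {
    bad <- lacunae_plan$diameter < 2 | lacunae_plan$diameter >= 15
    if (any(bad))
      warning(sum(bad), " planned lacuna(e) outside the detectable ",
              "diameter gate [2, 15) mm")
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = spacing,
    brain_semiaxes = brain_semiaxes * scale,
    ribbon_thickness = ribbon_thickness,
    ventricle_centers = ventricle_centers * scale,
    ventricle_semiaxes = ventricle_semiaxes * scale,
    lobe_planes = lapply(lobe_planes, function(v) v * scale),
    zone_targets = zone_targets,
    lacunae_plan = lacunae_plan, stroke_plan = stroke_plan,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_spec_bounds(spec)
  spec
}

grid_center_mm <- function(spec) (spec$grid_shape - 1) / 2 * spec$spacing

validate_spec_bounds <- function(spec) {
  cen <- grid_center_mm(spec)
  ext <- (spec$grid_shape - 1) * spec$spacing
  if (any(cen - spec$brain_semiaxes < 0) || any(cen + spec$brain_semiaxes > ext))
    stop("brain ellipsoid (semi-axes ",
         paste(format(spec$brain_semiaxes), collapse = ", "),
         " mm) exceeds the grid bounds; enlarge the grid or shrink the brain")
  for (i in seq_len(nrow(spec$ventricle_centers))) {
    vc <- cen + spec$ventricle_centers[i, ]
    vs <- spec$ventricle_semiaxes[i, ]
    if (any(vc - vs < 0) || any(vc + vs > ext))
      stop("ventricle ", i, " exceeds the grid bounds")
  }
  invisible(spec)
}

coord_grids <- function(grid_shape, spacing) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  list(
    x = array(rep((0:(nx - 1)) * spacing[1], times = ny * nz), grid_shape),
    y = array(rep(rep((0:(ny - 1)) * spacing[2], each = nx), times = nz),
              grid_shape),
    z = array(rep((0:(nz - 1)) * spacing[3], each = nx * ny), grid_shape)
  )
}

in_ellipsoid <- function(g, center, semi) {
  if (any(semi <= 0)) return(array(FALSE, dim(g$x)))
  ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2 <= 1
}

#' Build the labeled phantom volume
#'
#' Every voxel receives exactly one label from [LABELS]: background,
#' ventricle, one of four lobar white matter compartments, or cortical
#' gray. White matter is the interior of the pial ellipsoid shrunk by the
#' ribbon thickness, minus the ventricles; cortical gray is the closed
#' ellipsoidal shell outside it.
#'
#' @param spec A [phantom_spec()].
#' @return A `vol3d` of integer labels.
#' @export
make_label_volume <- function(spec) {
  g <- coord_grids(spec$grid_shape, spec$spacing)
  cen <- grid_center_mm(spec)
  brain <- in_ellipsoid(g, cen, spec$brain_semiaxes)
  wm_outer <- pmax(spec$brain_semiaxes - spec$ribbon_thickness, 0)
  inner <- in_ellipsoid(g, cen, wm_outer)
  vent <- array(FALSE, spec$grid_shape)
  for (i in seq_len(nrow(spec$ventricle_centers)))
    vent <- vent | in_ellipsoid(g, cen + spec$ventricle_centers[i, ],
                                spec$ventricle_semiaxes[i, ])
  vent <- vent & inner  # ventricles live inside the white matter envelope

  lab <- array(LABELS[["background"]], spec$grid_shape)
  lab[brain] <- LABELS[["cortex"]]
  wm <- inner & !vent
  # lobar split of white matter
  yc <- g$y - cen[2]; zc <- g$z - cen[3]
  frontal   <- wm & (yc >= spec$lobe_planes$frontal_y)
  occipital <- wm & (yc <= spec$lobe_planes$occipital_y)
  middle    <- wm & !frontal & !occipital
  parietal  <- middle & (zc > spec$lobe_planes$temporal_z)
  temporal  <- middle & !parietal
  lab[frontal]   <- LABELS[["wm_frontal"]]
  lab[parietal]  <- LABELS[["wm_parietal"]]
  lab[occipital] <- LABELS[["wm_occipital"]]
  lab[temporal]  <- LABELS[["wm_temporal"]]
  lab[vent] <- LABELS[["ventricle"]]
  vol3d(array(as.integer(lab), spec$grid_shape), spec$spacing)
}

ball_offsets <- function(r_mm, spacing) {
  # voxel offsets within a closed ball of radius r_mm, ordered by distance
  nr <- floor(r_mm / spacing)
  ox <- -nr[1]:nr[1]; oy <- -nr[2]:nr[2]; oz <- -nr[3]:nr[3]
  off <- expand.grid(dx = ox, dy = oy, dz = oz)
  d2 <- (off$dx * spacing[1])^2 + (off$dy * spacing[2])^2 +
        (off$dz * spacing[3])^2
  keep <- d2 <= r_mm^2
  off <- off[keep, , drop = FALSE]
  off[order(d2[keep]), , drop = FALSE]
}

#' Plant hyperintense lesions into depth zones
#'
#' Greedily places compact blob lesions (clipped spheres) wholly inside
#' each requested depth zone until the planted voxel count matches the
#' requested percentage of zonal white matter. Blobs keep at least
#' `min_blob` voxels so that planted lesions survive small-component
#' filtering in segmentation; a residual of fewer than `min_blob` voxels
#' is left unplanted (bounded by ~0.02 percentage points on these grids).
#'
#' @param labels Label `vol3d` from [make_label_volume()].
#' @param zones A `zone_set` from [zone_partition()] for the same labels.
#' @param zone_targets Percent of zonal WM per zone, named pv/deep/ic.
#' @param seed Integer seed.
#' @param radius_range Lesion radius range, mm.
#' @param min_blob Minimum voxels per planted blob.
#' @return A `ground_truth` object: `lesion_mask` (`vol3d` logical),
#'   `per_zone_fraction` (achieved percent, recomputed by voxel counting),
#'   `zone_targets`, and per-zone voxel counts.
#' @export
plant_lesions <- function(labels, zones, zone_targets, seed = 1L,
                          radius_range = c(1, 2.5), min_blob = 5L) {
  stopifnot(inherits(labels, "vol3d"), inherits(zones, "zone_set"))
  zone_targets <- zone_targets[c("pv", "deep", "ic")]
  if (any(is.na(zone_targets))) stop("zone_targets must be named pv, deep, ic")
  lesion <- array(FALSE, dim(labels$data))
  dims <- dim(labels$data)
  sp <- labels$spacing
  achieved <- c(pv = 0, deep = 0, ic = 0)
  counts <- integer(3); names(counts) <- names(achieved)
  with_seed(seed, {
    for (zn in names(zone_targets)) {
      zmask <- switch(zn, pv = zones$periventricular, deep = zones$deep,
                      ic = zones$infracortical)$data
      nz <- sum(zmask)
      if (zone_targets[[zn]] > 0 && nz == 0)
        stop("zone '", zn, "' is empty; planted target ", zone_targets[[zn]],
             "% is unreachable")
      target_vox <- round(zone_targets[[zn]] / 100 * nz)
      if (target_vox == 0) next
      placed <- 0L
      tries <- 0L
      idx_zone <- which(zmask)
      while (placed < target_vox) {
        tries <- tries + 1L
        if (tries > 500L)
          stop("could not reach the planted target in zone '", zn,
               "' after 500 placements; zone too small or too fragmented")
        remaining <- target_vox - placed
        cen_i <- arrayInd(sample(idx_zone, 1L), dims)
        r <- stats::runif(1, radius_range[1], radius_range[2])
        off <- ball_offsets(r, sp)
        vx <- cen_i[1] + off$dx; vy <- cen_i[2] + off$dy; vz <- cen_i[3] + off$dz
        ok <- vx >= 1 & vx <= dims[1] & vy >= 1 & vy <= dims[2] &
              vz >= 1 & vz <= dims[3]
        lin <- ((vz[ok] - 1) * dims[2] + (vy[ok] - 1)) * dims[1] + vx[ok]
        lin <- lin[zmask[lin] & !lesion[lin]]  # clip to zone, no double count
        take <- min(length(lin), remaining)
        # keep blobs at or above min_blob whenever the remainder allows it;
        # a residual below min_blob is planted as one final small fragment
        if (remaining >= min_blob && take < min_blob) next
        if (take < 1) next
        lesion[lin[seq_len(take)]] <- TRUE
        placed <- placed + take
      }
    }
  })
  # recount independently of the bookkeeping above
  for (zn in names(achieved)) {
    zmask <- switch(zn, pv = zones$periventricular, deep = zones$deep,
                    ic = zones$infracortical)$data
    counts[zn] <- sum(lesion & zmask)
    achieved[zn] <- if (sum(zmask) > 0) 100 * counts[zn] / sum(zmask) else 0
  }
  structure(list(
    lesion_mask = vol3d(lesion, sp),
    per_zone_fraction = achieved,
    zone_targets = zone_targets,
    lesion_voxels = counts
  ), class = "ground_truth")
}

#' Voxelize a lacunae plan into a dark-lesion mask
#'
#' @param labels Label `vol3d`.
#' @param plan Data frame with `x`, `y`, `z` center offsets (mm from grid
#'   center) and `diameter` (mm).
#' @return Logical `vol3d` mask of voxelized spheres (clipped to white
#'   matter) plus the analytic planted volume as attribute `true_volume_mm3`.
#' @export
make_lacunae_mask <- function(labels, plan) {
  mask <- array(FALSE, dim(labels$data))
  dims <- dim(labels$data)
  cen <- (dims - 1) / 2 * labels$spacing
  wm <- array(labels$data %in% WM_LABELS, dims)
  vol_true <- 0
  if (!is.null(plan) && nrow(plan) > 0) {
    for (i in seq_len(nrow(plan))) {
      c_mm <- cen + c(plan$x[i], plan$y[i], plan$z[i])
      ci <- round(c_mm / labels$spacing) + 1
      off <- ball_offsets(plan$diameter[i] / 2, labels$spacing)
      vx <- ci[1] + off$dx; vy <- ci[2] + off$dy; vz <- ci[3] + off$dz
      ok <- vx >= 1 & vx <= dims[1] & vy >= 1 & vy <= dims[2] &
            vz >= 1 & vz <= dims[3]
      lin <- ((vz[ok] - 1) * dims[2] + (vy[ok] - 1)) * dims[1] + vx[ok]
      mask[lin[wm[lin]]] <- TRUE
      vol_true <- vol_true + sphere_volume(plan$diameter[i])
    }
  }
  out <- vol3d(mask, labels$spacing)
  attr(out, "true_volume_mm3") <- vol_true
  out
}

#' Render a FLAIR-like intensity volume
#'
#' Voxel intensity = tissue mean (lesion mean where the lesion mask is set,
#' lacuna mean where the dark mask is set) plus iid Gaussian noise.
#'
#' @param labels Label `vol3d`.
#' @param lesions Logical `vol3d` of hyperintense lesions (or NULL).
#' @param tissue_means Named intensity means; see [default_tissue_means()].
#' @param noise_sd Gaussian noise SD (0 for a noiseless render).
#' @param seed Integer seed.
#' @param dark_mask Optional logical `vol3d` of dark (lacunar) lesions.
#' @return Numeric `vol3d`.
#' @export
render_flair <- function(labels, lesions = NULL,
                         tissue_means = default_tissue_means(),
                         noise_sd = 0, seed = 1L, dark_mask = NULL) {
  stopifnot(inherits(labels, "vol3d"))
  need <- names(LABELS)
  if (!all(need %in% names(tissue_means)))
    stop("tissue_means must name every label: ",
         paste(setdiff(need, names(tissue_means)), collapse = ", "))
  img <- array(0, dim(labels$data))
  for (nm in need) img[labels$data == LABELS[[nm]]] <- tissue_means[[nm]]
  if (!is.null(lesions)) {
    stop_if_grid_mismatch(labels, lesions, "labels and lesion mask")
    wm_means <- tissue_means[c("wm_frontal", "wm_parietal", "wm_occipital",
                               "wm_temporal")]
    if (tissue_means[["lesion"]] <= max(wm_means))
      stop("lesion mean must be strictly above the white matter mean")
    img[lesions$data] <- tissue_means[["lesion"]]
  }
  if (!is.null(dark_mask)) {
    stop_if_grid_mismatch(labels, dark_mask, "labels and dark mask")
    img[dark_mask$data] <- tissue_means[["lacuna"]]
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, array(stats::rnorm(length(img), 0, noise_sd),
                                       dim(img)))
  vol3d(img, labels$spacing)
}

#' Generate a complete single-subject phantom
#'
#' Convenience wrapper: labels, depth zones, planted lesions, lacunae mask,
#' and the rendered FLAIR-like volume, with ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param zoning Optional [zone_params()] controlling band widths.
#' @return List with `labels`, `zones`, `truth`, `lacunae_mask`, `flair`,
#'   and the originating `spec`.
#' @export
make_phantom <- function(spec, zoning = zone_params()) {
  labels <- make_label_volume(spec)
  zones <- zone_partition(labels, zoning)
  truth <- plant_lesions(labels, zones, spec$zone_targets,
                         seed = spec$seed + 1L)
  lac <- make_lacunae_mask(labels, spec$lacunae_plan)
  flair <- render_flair(labels, truth$lesion_mask,
                        noise_sd = spec$noise_sd, seed = spec$seed + 2L,
                        dark_mask = lac)
  list(spec = spec, labels = labels, zones = zones, truth = truth,
       lacunae_mask = lac, flair = flair)
}
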