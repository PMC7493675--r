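# Regional LA quantification (percent of zonal white matter), lacunae
# detection and volumetrics, and stroke volume by the two-diameter rule.

sphere_volume <- function(d) (4 / 3) * pi * (d / 2)^3

#' LA volume as a percentage of a region's white matter
#'
#' `100 * volume(la n region) / volume(region)`, volumes in mm^3 via the
#' shared voxel spacing.
#'
#' @param la Logical `vol3d` lesion mask.
#' @param region Logical `vol3d` region mask (non-empty) on the same grid.
#' @return Percentage in \[0, 100\].
#' @export
la_fraction <- function(la, region) {
  stopifnot(inherits(la, "vol3d"), inherits(region, "vol3d"))
  stop_if_grid_mismatch(la, region, "lesion and region masks")
  nr <- sum(region$data)
  if (nr == 0) stop("region mask is empty; the LA fraction is undefined")
  100 * sum(la$data & region$data) / nr
}

#' Regional LA profile
#'
#' All six regional fractions (total, periventricular, deep, infracortical,
#' anterior, posterior) plus absolute LA and white matter volumes. Zone
#' fractions use zonal white matter denominators; the total uses the full
#' white matter mask. The lesion mask is intersected with white matter
#' throughout.
#'
#' @param la Logical `vol3d` lesion mask.
#' @param zones A `zone_set` on the same grid.
#' @return An `la_profile` object (also a plain named list).
#' @export
la_profile <- function(la, zones) {
  stopifnot(inherits(zones, "zone_set"))
  stop_if_grid_mismatch(la, zones$wm, "lesion mask and zones")
  vv <- voxel_volume(la)
  la_wm <- vol3d(la$data & zones$wm$data, la$spacing)
  frac_or_na <- function(region)
    if (sum(region$data) > 0) la_fraction(la_wm, region) else NA_real_
  structure(list(
    total_pct     = la_fraction(la_wm, zones$wm),
    pv_pct        = frac_or_na(zones$periventricular),
    deep_pct      = frac_or_na(zones$deep),
    ic_pct        = frac_or_na(zones$infracortical),
    anterior_pct  = frac_or_na(zones$anterior),
    posterior_pct = frac_or_na(zones$posterior),
    la_volume_mm3 = sum(la_wm$data) * vv,
    wm_volume_mm3 = sum(zones$wm$data) * vv
  ), class = "la_profile")
}

#' @export
print.la_profile <- function(x, ...) {
  cat(sprintf(paste0("LA profile: total %.3f%% | PV %.3f%% | deep %.3f%% | ",
                     "IC %.3f%%\n  anterior %.3f%% | posterior %.3f%% | ",
                     "LA %.0f mm^3 of WM %.0f mm^3\n"),
              x$total_pct, x$pv_pct, x$deep_pct, x$ic_pct,
              x$anterior_pct, x$posterior_pct,
              x$la_volume_mm3, x$wm_volume_mm3))
  invisible(x)
}

#' Lacuna volume from its diameter
#'
#' Spherical volume `(4/3) * pi * (d/2)^3` for a lacuna whose diameter lies
#' inside the lacunar gate: at least 2 mm and strictly below 15 mm.
#'
#' @param diameter_mm Diameter(s) in mm.
#' @return Volume(s) in mm^3.
#' @export
lacuna_volume <- function(diameter_mm) {
  if (any(diameter_mm < 2))
    stop("diameter below the 2 mm lacunar gate (too small)")
  if (any(diameter_mm >= 15))
    stop("diameter at or above the 15 mm lacunar gate (too large; ",
         "measure as a stroke instead)")
  sphere_volume(diameter_mm)
}

#' Detect lacunae in a dark-lesion mask
#'
#' 3-D connected components (26-connectivity) whose equivalent-sphere
#' diameter lies in the \[2, 15) mm gate and which extend over at least
#' `min_slices` axial slices (the stationarity rule) are retained. Each
#' lacuna's volume is the spherical volume of its equivalent diameter, and
#' its zone tag is read from the zone labelmap at its centroid (or by
#' majority vote over its voxels).
#'
#' @param dark_mask Logical `vol3d` of candidate dark lesions.
#' @param min_slices Minimum axial slice extent (default 2).
#' @param zone_map Optional integer `vol3d` from [zone_labelmap()].
#' @param tag_by `"centroid"` (default) or `"majority"`.
#' @return A `lesion_set`: data frame of per-lesion records (centroid
#'   voxel indices, equivalent diameter mm, slice extent, zone tag, volume
#'   mm^3) with attribute `summed_volume_mm3`.
#' @export
detect_lacunae <- function(dark_mask, min_slices = 2L, zone_map = NULL,
                           tag_by = c("centroid", "majority")) {
  stopifnot(inherits(dark_mask, "vol3d"))
  tag_by <- match.arg(tag_by)
  zone_names <- c("0" = "other", "1" = "periventricular", "2" = "deep",
                  "3" = "infracortical")
  empty <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      cz = numeric(), n_voxels = integer(),
                      equiv_diameter_mm = numeric(), slice_extent = integer(),
                      zone = character(), volume_mm3 = numeric())
  if (!any(dark_mask$data)) {
    attr(empty, "summed_volume_mm3") <- 0
    class(empty) <- c("lesion_set", class(empty))
    return(empty)
  }
  comp <- label_components(dark_mask)
  vv <- voxel_volume(dark_mask)
  ids <- sort(unique(comp$data[comp$data > 0L]))
  rows <- lapply(ids, function(i) {
    idx <- which(comp$data == i)
    pos <- arrayInd(idx, dim(comp$data))
    n <- length(idx)
    d_eq <- 2 * (3 * n * vv / (4 * pi))^(1 / 3)
    extent <- length(unique(pos[, 3]))
    if (d_eq < 2 || d_eq >= 15 || extent < min_slices) return(NULL)
    zone <- "other"
    if (!is.null(zone_map)) {
      code <- if (tag_by == "centroid") {
        cen <- round(colMeans(pos))
        zone_map$data[cen[1], cen[2], cen[3]]
      } else {
        codes <- zone_map$data[idx]
        as.integer(names(which.max(table(codes))))
      }
      zone <- zone_names[[as.character(code)]]
    }
    data.frame(id = i, cx = mean(pos[, 1]), cy = mean(pos[, 2]),
               cz = mean(pos[, 3]), n_voxels = n, equiv_diameter_mm = d_eq,
               slice_extent = extent, zone = zone,
               volume_mm3 = lacuna_volume(d_eq))
  })
  out <- do.call(rbind, c(list(empty), rows))
  attr(out, "summed_volume_mm3") <- sum(out$volume_mm3)
  class(out) <- c("lesion_set", class(out))
  out
}

#' Stroke volume by the two-diameter approach
#'
#' `correction * d1 * d2 * n_slices * slice_thickness / 1000`: two in-plane
#' diameters multiplied by the through-plane extent (slice count times
#' slice thickness), converted from mm^3 to mL. The default correction of
#' 1.0 is the literal two-diameter product; 0.5 gives the ABC/2 ellipsoid
#' convention.
#'
#' @param d1_mm,d2_mm In-plane diameters, mm (>= 0).
#' @param n_slices Number of slices the lesion spans (>= 0).
#' @param slice_thickness_mm Slice thickness, mm (>= 0).
#' @param correction Multiplicative correction factor.
#' @return Volume in mL.
#' @export
stroke_volume <- function(d1_mm, d2_mm, n_slices, slice_thickness_mm = 1,
                          correction = 1) {
  if (any(c(d1_mm, d2_mm, n_slices, slice_thickness_mm) < 0))
    stop("stroke measurements must be non-negative")
  correction * d1_mm * d2_mm * n_slices * slice_thickness_mm / 1000
}
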