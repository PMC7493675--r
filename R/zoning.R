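# Depth zoning of white matter: periventricular / deep / infracortical
# bands in physical mm, and the anterior/posterior lobe partition.

#' Depth-zone construction parameters
#'
#' Band widths in mm and the precedence rule applied where the two border
#' bands overlap. Membership uses the closed ball (distance <= width).
#' The periventricular and infracortical widths both default to 5 mm, the
#' operational band definitions; the infracortical width may be narrowed
#' (e.g. to 2 mm) to mirror a boundary-inflation construction instead.
#'
#' @param pv_width_mm Periventricular band width, mm (>= 0).
#' @param ic_width_mm Infracortical band width, mm (>= 0).
#' @param precedence `"pv"` (default) assigns voxels falling in both bands
#'   to the periventricular zone; `"ic"` assigns them infracortically.
#' @return A `zone_params` object.
#' @export
zone_params <- function(pv_width_mm = 5, ic_width_mm = 5,
                        precedence = c("pv", "ic")) {
  if (pv_width_mm < 0 || ic_width_mm < 0) stop("band widths must be >= 0")
  structure(list(pv_width_mm = pv_width_mm, ic_width_mm = ic_width_mm,
                 precedence = match.arg(precedence)),
            class = "zone_params")
}

wm_mask <- function(labels) {
  vol3d(array(labels$data %in% WM_LABELS, dim(labels$data)), labels$spacing)
}

#' Periventricular band mask
#'
#' White matter voxels within `width_mm` (Euclidean, spacing-aware) of the
#' nearest ventricle voxel, excluding the ventricle itself. An empty
#' ventricle, or a zero width, gives an empty mask.
#'
#' @param labels Label `vol3d`.
#' @param width_mm Band width, mm.
#' @return Logical `vol3d`.
#' @export
periventricular_mask <- function(labels, width_mm = 5) {
  stopifnot(inherits(labels, "vol3d"))
  vent <- vol3d(array(labels$data == LABELS[["ventricle"]], dim(labels$data)),
                labels$spacing)
  wm <- wm_mask(labels)
  if (!any(vent$data) || width_mm <= 0)
    return(vol3d(array(FALSE, dim(labels$data)), labels$spacing))
  d2 <- edt_squared(vent)
  vol3d(wm$data & d2$data <= width_mm^2 & !vent$data, labels$spacing)
}

#' Infracortical band mask
#'
#' White matter voxels within `width_mm` (Euclidean, spacing-aware) of the
#' nearest cortical gray matter voxel.
#'
#' @param labels Label `vol3d`.
#' @param width_mm Band width, mm.
#' @return Logical `vol3d`.
#' @export
infracortical_mask <- function(labels, width_mm = 5) {
  stopifnot(inherits(labels, "vol3d"))
  ctx <- vol3d(array(labels$data == LABELS[["cortex"]], dim(labels$data)),
               labels$spacing)
  if (!any(ctx$data))
    stop("no cortical gray matter voxels in the label volume; ",
         "cannot build the infracortical band")
  wm <- wm_mask(labels)
  if (width_mm <= 0)
    return(vol3d(array(FALSE, dim(labels$data)), labels$spacing))
  d2 <- edt_squared(ctx)
  vol3d(wm$data & d2$data <= width_mm^2, labels$spacing)
}

#' Partition white matter into the three depth zones
#'
#' Periventricular and infracortical bands are built first; voxels claimed
#' by both are resolved by `params$precedence`; deep white matter is the
#' remainder. The three masks are pairwise disjoint and their union is
#' exactly the white matter mask. Also attaches the anterior (frontal) and
#' posterior (parietal + occipital) lobe masks.
#'
#' @param labels Label `vol3d` containing ventricle, white matter, and
#'   cortical gray labels.
#' @param params A [zone_params()].
#' @return A `zone_set`: logical `vol3d` masks `periventricular`, `deep`,
#'   `infracortical`, `anterior`, `posterior`, and `wm`.
#' @export
zone_partition <- function(labels, params = zone_params()) {
  pv <- periventricular_mask(labels, params$pv_width_mm)
  ic <- infracortical_mask(labels, params$ic_width_mm)
  if (params$precedence == "pv") {
    ic <- vol3d(ic$data & !pv$data, labels$spacing)
  } else {
    pv <- vol3d(pv$data & !ic$data, labels$spacing)
  }
  wm <- wm_mask(labels)
  deep <- vol3d(wm$data & !pv$data & !ic$data, labels$spacing)
  ap <- anterior_posterior_masks(labels)
  structure(list(periventricular = pv, deep = deep, infracortical = ic,
                 anterior = ap$anterior, posterior = ap$posterior, wm = wm,
                 params = params),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  n <- vapply(x[c("periventricular", "deep", "infracortical",
                  "anterior", "posterior", "wm")],
              function(m) sum(m$data), numeric(1))
  cat("zone_set (voxels): PV", n[1], "| deep", n[2], "| IC", n[3],
      "| anterior", n[4], "| posterior", n[5], "| WM", n[6], "\n")
  invisible(x)
}

#' Anterior and posterior white matter masks
#'
#' Anterior is frontal-lobe white matter only; posterior is the union of
#' parietal and occipital white matter. Temporal white matter belongs to
#' neither.
#'
#' @param labels Label `vol3d` with lobar white matter codes.
#' @return List of logical `vol3d` masks `anterior` and `posterior`.
#' @export
anterior_posterior_masks <- function(labels) {
  stopifnot(inherits(labels, "vol3d"))
  if (!any(labels$data %in% WM_LABELS))
    stop("label volume contains no white matter voxels")
  ant <- labels$data == LABELS[["wm_frontal"]]
  pos <- labels$data == LABELS[["wm_parietal"]] |
         labels$data == LABELS[["wm_occipital"]]
  list(anterior = vol3d(array(ant, dim(labels$data)), labels$spacing),
       posterior = vol3d(array(pos, dim(labels$data)), labels$spacing))
}

#' Depth-zone labelmap
#'
#' Single integer volume encoding the partition: 1 = periventricular,
#' 2 = deep, 3 = infracortical, 0 = outside white matter.
#'
#' @param zones A `zone_set`.
#' @return Integer `vol3d`.
#' @export
zone_labelmap <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  lab <- array(0L, dim(zones$wm$data))
  lab[zones$periventricular$data] <- 1L
  lab[zones$deep$data] <- 2L
  lab[zones$infracortical$data] <- 3L
  vol3d(lab, zones$wm$spacing)
}
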