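# Phantom generation: label partition, geometry oracle, lesion planting,
# FLAIR rendering, cohort simulation.

test_that("labels partition the grid: disjoint and exhaustive", {
  lab <- make_label_volume(small_spec())
  hist <- table(factor(lab$data, levels = LABELS))
  expect_equal(sum(hist), prod(dim(lab$data)))
  expect_true(all(lab$data %in% LABELS))
})

test_that("zero ventricle semi-axes give zero ventricle voxels", {
  sp <- small_spec()
  sp$ventricle_semiaxes[] <- 0
  lab <- make_label_volume(sp)
  expect_equal(sum(lab$data == LABELS[["ventricle"]]), 0)
})

test_that("geometry exceeding the grid bounds is rejected", {
  expect_error(phantom_spec(grid_shape = c(20, 20, 20)), "exceeds the grid")
  sp <- small_spec()
  sp$ventricle_centers[1, ] <- c(50, 0, 0)
  expect_error(validate_spec_bounds(sp), "ventricle")
})

test_that("white matter count matches direct per-voxel predicate evaluation", {
  spec <- small_spec()
  lab <- make_label_volume(spec)
  # oracle: evaluate the parametric inclusion predicates voxel by voxel
  cen <- (spec$grid_shape - 1) / 2 * spec$spacing
  n_wm <- 0L
  for (i in 0:(spec$grid_shape[1] - 1))
    for (j in 0:(spec$grid_shape[2] - 1))
      for (k in 0:(spec$grid_shape[3] - 1)) {
        p <- c(i, j, k) * spec$spacing - cen
        inner <- spec$brain_semiaxes - spec$ribbon_thickness
        in_wm_env <- sum((p / inner)^2) <= 1
        in_vent <- FALSE
        for (v in 1:2) {
          q <- p - spec$ventricle_centers[v, ]
          if (sum((q / spec$ventricle_semiaxes[v, ])^2) <= 1) in_vent <- TRUE
        }
        if (in_wm_env && !in_vent) n_wm <- n_wm + 1L
      }
  expect_equal(sum(lab$data %in% WM_LABELS), n_wm)
})

test_that("white matter is one connected component surrounding the ventricles", {
  lab <- make_label_volume(small_spec())
  wm <- mask_of(lab, function(d) d %in% WM_LABELS)
  comp <- label_components(wm)
  expect_equal(max(comp$data), 1L)
  expect_gt(sum(lab$data == LABELS[["ventricle"]]), 0)
})

test_that("null lesion plan yields an empty mask and zero fractions", {
  lab <- make_label_volume(small_spec())
  zones <- zone_partition(lab, zone_params(pv_width_mm = 3, ic_width_mm = 3))
  gt <- plant_lesions(lab, zones, c(pv = 0, deep = 0, ic = 0))
  expect_false(any(gt$lesion_mask$data))
  expect_equal(unname(gt$per_zone_fraction), c(0, 0, 0))
})

test_that("planted deep fraction verified by independent voxel counting", {
  lab <- make_label_volume(small_spec())
  zones <- zone_partition(lab, zone_params(pv_width_mm = 2, ic_width_mm = 2))
  gt <- plant_lesions(lab, zones, c(pv = 0, deep = 2, ic = 0), seed = 5)
  n_deep <- sum(zones$deep$data)
  n_les <- sum(gt$lesion_mask$data & zones$deep$data)
  expect_equal(gt$per_zone_fraction[["deep"]], 100 * n_les / n_deep)
  expect_lt(abs(gt$per_zone_fraction[["deep"]] - 2) / 2, 0.10)
  # lesions wholly inside the requested zone
  expect_equal(sum(gt$lesion_mask$data), n_les)
})

test_that("unreachable planting targets raise an error naming the zone", {
  sp <- small_spec()
  sp$ventricle_semiaxes[] <- 0  # no ventricles -> empty periventricular zone
  lab <- make_label_volume(sp)
  zones <- zone_partition(lab, zone_params(pv_width_mm = 3, ic_width_mm = 3))
  expect_error(plant_lesions(lab, zones, c(pv = 5, deep = 0, ic = 0)),
               "'pv'")
})

test_that("noiseless rendering reproduces configured means exactly", {
  lab <- make_label_volume(small_spec())
  zones <- zone_partition(lab, zone_params(pv_width_mm = 3, ic_width_mm = 3))
  gt <- plant_lesions(lab, zones, c(pv = 0, deep = 3, ic = 0), seed = 2)
  tm <- default_tissue_means()
  fl <- render_flair(lab, gt$lesion_mask, tm, noise_sd = 0)
  expect_equal(unique(fl$data[gt$lesion_mask$data]), tm[["lesion"]])
  wm_clean <- lab$data %in% WM_LABELS & !gt$lesion_mask$data
  expect_equal(unique(fl$data[wm_clean]), tm[["wm_frontal"]])
  # configured lesion-WM gap is realized exactly
  expect_equal(min(fl$data[gt$lesion_mask$data]) - max(fl$data[wm_clean]),
               tm[["lesion"]] - tm[["wm_frontal"]])
})

test_that("rendering with a fixed seed is byte-identical across runs", {
  lab <- make_label_volume(small_spec())
  a <- render_flair(lab, NULL, noise_sd = 4, seed = 9)
  b <- render_flair(lab, NULL, noise_sd = 4, seed = 9)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("rendering validates tissue means", {
  lab <- make_label_volume(small_spec())
  expect_error(render_flair(lab, NULL, tissue_means = c(background = 0)),
               "every label")
})

test_that("cohort preset carries the study conditions", {
  spec <- cohort_preset("af-pilot")
  expect_equal(unname(spec$n_per_group), c(17L, 17L))
  expect_equal(unname(spec$zone_means["AF", "ic"]), 0.72)
  expect_equal(unname(spec$zone_means["non-AF", "ic"]), 0.07)
  expect_equal(unname(spec$zone_means["AF", "pv"]), 15.6)
  expect_error(cohort_preset("nope"), "unknown")
})

test_that("cohort simulation is deterministic and arm-independent", {
  a <- simulate_cohort(seed = 4)
  b <- simulate_cohort(seed = 4)
  expect_identical(a, b)
  af <- simulate_cohort(seed = 4, groups = "AF")
  expect_equal(af$planted_total, a$planted_total[a$group == "AF"])
})

test_that("empirical draws hit the preset group means exactly", {
  tab <- simulate_cohort(seed = 6)
  spec <- cohort_preset()
  for (g in c("AF", "non-AF")) {
    rows <- tab$group == g
    expect_equal(mean(tab$planted_pv[rows]), spec$zone_means[g, "pv"],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(mean(tab$planted_ic[rows]), spec$zone_means[g, "ic"],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(mean(tab$ticv_mm3[rows]), spec$ticv[g, "mean"],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sd(tab$ticv_mm3[rows]), spec$ticv[g, "sd"],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("shrinking dispersion collapses draws onto the group means", {
  spec <- cohort_spec(zone_cv = 1e-4, empirical = FALSE)
  tab <- simulate_cohort(spec, seed = 8)
  af <- tab$group == "AF"
  expect_equal(mean(tab$planted_deep[af]), 2.1, tolerance = 1e-3)
  expect_lt(sd(tab$planted_deep[af]) / mean(tab$planted_deep[af]), 1e-3)
})

test_that("cohort spec rejects invalid dispersions and group sizes", {
  expect_error(cohort_spec(zone_cv = 0), "positive")
  expect_error(cohort_spec(n_per_group = c(A = 1L, B = 17L)), ">= 2")
})
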