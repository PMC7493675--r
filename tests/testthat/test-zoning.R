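# Depth zoning: band oracles, partition identity, precedence,
# anterior/posterior masks.

test_that("periventricular band matches the all-pairs distance oracle", {
  # single ventricle voxel at the center of an 11^3 grid, anisotropic
  for (sp in list(c(1, 1, 1), c(1, 1, 2), c(0.5, 1, 2))) {
    lab <- toy_labels(c(11, 11, 11), sp, fill = LABELS[["wm_frontal"]])
    lab <- set_label(lab, "ventricle", 6, 6, 6)
    lab <- set_label(lab, "cortex", 1, 1, 1)
    got <- periventricular_mask(lab, 5)
    want <- brute_band(lab, "ventricle", 5, exclude_target = TRUE)
    expect_identical(got$data, want$data)
  }
})

test_that("infracortical band matches the oracle on slab geometry", {
  # GM slab abutting a WM slab; band thickness counts layers by mm
  for (sp in list(c(1, 1, 1), c(1, 1, 2), c(2, 1, 1))) {
    lab <- toy_labels(c(10, 5, 5), sp, fill = LABELS[["background"]])
    lab$data[1:2, , ] <- LABELS[["cortex"]]
    lab$data[3:10, , ] <- LABELS[["wm_parietal"]]
    got <- infracortical_mask(lab, 2)
    want <- brute_band(lab, "cortex", 2)
    expect_identical(got$data, want$data)
    # layer count along the slab normal = floor(width / spacing_x)
    expect_equal(sum(got$data) / (5 * 5), floor(2 / sp[1]))
  }
})

test_that("zero-width bands are empty", {
  lab <- make_label_volume(small_spec())
  expect_false(any(periventricular_mask(lab, 0)$data))
  expect_false(any(infracortical_mask(lab, 0)$data))
})

test_that("band edge cases: empty ventricle, missing cortex", {
  sp <- small_spec()
  sp$ventricle_semiaxes[] <- 0
  lab <- make_label_volume(sp)
  expect_false(any(periventricular_mask(lab, 5)$data))
  lab2 <- toy_labels(c(5, 5, 5), fill = LABELS[["wm_frontal"]])
  expect_error(infracortical_mask(lab2, 5), "cortical gray")
})

test_that("band masks grow monotonically with width", {
  lab <- make_label_volume(small_spec())
  prev <- periventricular_mask(lab, 0)
  for (w in c(1, 2, 4, 6)) {
    cur <- periventricular_mask(lab, w)
    expect_true(all(cur$data[prev$data]))
    prev <- cur
  }
})

test_that("zone partition is disjoint and exhaustive over white matter", {
  lab <- make_label_volume(small_spec())
  for (par in list(zone_params(), zone_params(3, 3), zone_params(5, 2))) {
    z <- zone_partition(lab, par)
    n <- sum(z$periventricular$data) + sum(z$deep$data) +
      sum(z$infracortical$data)
    expect_equal(n, sum(z$wm$data))
    expect_false(any(z$periventricular$data & z$infracortical$data))
    expect_false(any(z$periventricular$data & z$deep$data))
    expect_false(any(z$deep$data & z$infracortical$data))
    expect_true(all(z$wm$data[z$periventricular$data]))
  }
})

test_that("zero-width bands make deep equal to all of white matter", {
  lab <- make_label_volume(small_spec())
  z <- zone_partition(lab, zone_params(0, 0))
  expect_identical(z$deep$data, z$wm$data)
})

test_that("precedence decides contested voxels and flipping swaps them", {
  # thin WM corridor between a ventricle voxel and a cortex slab so the
  # two 5 mm bands overlap
  lab <- toy_labels(c(13, 7, 7), fill = LABELS[["background"]])
  lab$data[2:12, 2:6, 2:6] <- LABELS[["wm_frontal"]]
  lab <- set_label(lab, "ventricle", 3, 4, 4)
  lab$data[12:13, , ] <- LABELS[["cortex"]]
  pv <- periventricular_mask(lab, 5)
  ic <- infracortical_mask(lab, 5)
  contested <- pv$data & ic$data
  expect_gt(sum(contested), 0)
  z_pv <- zone_partition(lab, zone_params(5, 5, precedence = "pv"))
  z_ic <- zone_partition(lab, zone_params(5, 5, precedence = "ic"))
  expect_true(all(z_pv$periventricular$data[contested]))
  expect_false(any(z_pv$infracortical$data[contested]))
  expect_true(all(z_ic$infracortical$data[contested]))
  expect_false(any(z_ic$periventricular$data[contested]))
  # off the contested set, the partitions agree
  expect_identical(z_pv$deep$data, z_ic$deep$data)
})

test_that("anterior/posterior masks follow the lobe labels", {
  lab <- make_label_volume(small_spec())
  ap <- anterior_posterior_masks(lab)
  expect_false(any(ap$anterior$data & ap$posterior$data))
  temporal <- lab$data == LABELS[["wm_temporal"]]
  expect_gt(sum(temporal), 0)
  expect_false(any(ap$anterior$data[temporal]))
  expect_false(any(ap$posterior$data[temporal]))
  expect_identical(ap$anterior$data,
                   array(lab$data == LABELS[["wm_frontal"]], dim(lab$data)))
})

test_that("empty occipital compartment leaves posterior = parietal", {
  lab <- toy_labels(c(8, 8, 8), fill = LABELS[["background"]])
  lab$data[2:7, 2:4, 2:7] <- LABELS[["wm_parietal"]]
  lab$data[2:7, 5:7, 2:7] <- LABELS[["wm_frontal"]]
  ap <- anterior_posterior_masks(lab)
  expect_identical(ap$posterior$data,
                   array(lab$data == LABELS[["wm_parietal"]], dim(lab$data)))
  expect_error(anterior_posterior_masks(toy_labels(c(4, 4, 4))),
               "no white matter")
})

test_that("zone labelmap encodes the partition", {
  lab <- make_label_volume(small_spec())
  z <- zone_partition(lab, zone_params(3, 3))
  zm <- zone_labelmap(z)
  expect_equal(sum(zm$data == 1L), sum(z$periventricular$data))
  expect_equal(sum(zm$data == 2L), sum(z$deep$data))
  expect_equal(sum(zm$data == 3L), sum(z$infracortical$data))
  expect_equal(sum(zm$data > 0L), sum(z$wm$data))
})

test_that("doubling spacing along one axis halves the band's voxel extent", {
  mk <- function(sp) {
    lab <- toy_labels(c(5, 5, 21), sp, fill = LABELS[["wm_frontal"]])
    lab$data[, , 1] <- LABELS[["ventricle"]]
    sum(periventricular_mask(lab, 8)$data) / (5 * 5)
  }
  expect_equal(mk(c(1, 1, 1)), 8)   # layers 2..9 at 1 mm
  expect_equal(mk(c(1, 1, 2)), 4)   # layers at 2,4,6,8 mm
})
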