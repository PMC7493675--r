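# Two-group cohort simulation: per-subject planted zone loads, head-size
# (TICV) variation, lobe cortical thickness with a planted TICV-adjusted
# partial correlation against total LA, lacunae/stroke volumetrics, and
# demographic/clinical columns.

# Depth-zone volume shares of white matter under the default phantom
# geometry (voxel-counted once from make_label_volume/zone_partition).
# Used to convert per-zone planted fractions into the implied total.
REF_ZONE_SHARES <- c(pv = 0.0538, deep = 0.4428, ic = 0.5034)

#' Specify a synthetic two-group cohort
#'
#' Defaults are the `"af-pilot"` preset: a 17 + 17 cohort of atrial
#' fibrillation (AF) patients and non-AF peers whose group mean zone LA
#' loads, TICV, demographics and clinical scores follow the published
#' group summary statistics of a pilot AF neuroimaging cohort. Per-subject
#' zone loads are log-normal (LA volumes are strongly right-skewed);
#' with `empirical = TRUE` (default) draws are rescaled so each group's
#' sample mean matches the preset mean exactly, so that fixed-seed
#' recovery runs measure the pipeline rather than sampling noise.
#'
#' @param n_per_group Named integer vector, subjects per group.
#' @param zone_means Matrix (groups x pv/deep/ic) of mean planted LA
#'   percent of zonal white matter.
#' @param zone_cv Per-subject coefficient of variation of zone loads.
#' @param ticv Matrix (groups x mean/sd) of total intracranial volume, mm^3.
#' @param thickness List with `means`, `sds` (per lobe, mm), `partial_r`
#'   (planted TICV-adjusted partial correlation of each lobe's thickness
#'   with log total LA), and `ticv_beta` (standardized TICV slope).
#' @param stroke,lacunae Lists: `presence` (per group, probability a
#'   subject has any lesion) and `meanlog`/`sdlog` of the log-normal
#'   volume (mL) among affected subjects.
#' @param clinical List of per-group mean/sd pairs for age, education,
#'   MoCA, WTAR, Charlson, and `sex_mf` male:female counts.
#' @param noise_sd Phantom intensity noise SD.
#' @param empirical Match group sample moments exactly (see above).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(
    n_per_group = c("AF" = 17L, "non-AF" = 17L),
    zone_means = rbind("AF" = c(pv = 15.6, deep = 2.1, ic = 0.72),
                       "non-AF" = c(pv = 10.8, deep = 0.6, ic = 0.07)),
    zone_cv = 0.8,
    ticv = rbind("AF" = c(mean = 1615269, sd = 178016),
                 "non-AF" = c(mean = 1605508, sd = 137530)),
    thickness = list(
      means = c(frontal = 2.6, parietal = 2.4, temporal = 2.9,
                occipital = 2.1),
      sds = c(frontal = 0.15, parietal = 0.15, temporal = 0.18,
              occipital = 0.12),
      partial_r = c(frontal = 0, parietal = 0, temporal = -0.37,
                    occipital = 0),
      ticv_beta = 0.3),
    stroke = list(presence = c("AF" = 11 / 17, "non-AF" = 0),
                  meanlog = log(45), sdlog = 0.8),
    lacunae = list(presence = c("AF" = 9 / 17, "non-AF" = 0),
                   meanlog = log(1.114) - 0.72, sdlog = 1.2),
    clinical = list(
      age = rbind("AF" = c(67.7, 8.0), "non-AF" = c(68.2, 4.8)),
      education = rbind("AF" = c(13.5, 2.9), "non-AF" = c(14.4, 2.0)),
      moca = rbind("AF" = c(24.3, 5.5), "non-AF" = c(26.8, 1.8)),
      wtar = rbind("AF" = c(37.6, 8.9), "non-AF" = c(38.6, 10.0)),
      charlson = rbind("AF" = c(1.8, 0.95), "non-AF" = c(0.24, 0.44)),
      sex_mf = rbind("AF" = c(11, 6), "non-AF" = c(11, 6))),
    noise_sd = 6,
    empirical = TRUE) {
  if (any(n_per_group < 2)) stop("group sizes must be >= 2")
  if (zone_cv <= 0) stop("zone_cv must be positive")
  if (any(zone_means < 0 | zone_means > 100))
    stop("zone means must lie in [0, 100] percent")
  structure(list(n_per_group = n_per_group, zone_means = zone_means,
                 zone_cv = zone_cv, ticv = ticv, thickness = thickness,
                 stroke = stroke, lacunae = lacunae, clinical = clinical,
                 noise_sd = noise_sd, empirical = isTRUE(empirical)),
            class = "cohort_spec")
}

#' Named cohort presets
#'
#' `"af-pilot"` is the default [cohort_spec()]: 17 AF vs 17 non-AF
#' subjects with published group-mean zone loads (periventricular
#' 15.6/10.8, deep 2.1/0.6, infracortical 0.72/0.07 percent).
#'
#' @param name Preset name.
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(name = "af-pilot") {
  switch(name,
         "af-pilot" = cohort_spec(),
         stop("unknown cohort preset: ", name))
}

rescale_moments <- function(x, mean_target, sd_target = NULL) {
  if (length(x) < 2) return(x)
  if (is.null(sd_target)) return(x * mean_target / mean(x))
  (x - mean(x)) / stats::sd(x) * sd_target + mean_target
}

draw_lognormal_mean <- function(n, m, cv, empirical) {
  if (m == 0) return(rep(0, n))
  sdlog <- sqrt(log(1 + cv^2))
  x <- stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
  if (empirical) x <- rescale_moments(x, m)
  x
}

# exact planting of a TICV-adjusted partial correlation:
# resid = r * std(resid of v on z) + sqrt(1-r^2) * std(orthogonalized noise)
plant_partial <- function(v, z, r, n) {
  u <- stats::lm.fit(cbind(1, z), v)$residuals
  u <- u / stats::sd(u)
  u <- u - mean(u)
  eps <- stats::rnorm(n)
  eps <- stats::lm.fit(cbind(1, z, u), eps)$residuals
  eps <- eps / stats::sd(eps)
  r * u + sqrt(1 - r^2) * eps
}

decompose_lacunae <- function(target_mm3, max_n = 24L) {
  diam <- numeric(0)
  rem <- target_mm3
  while (rem >= sphere_volume(2.2) && length(diam) < max_n) {
    d <- stats::runif(1, 3, 9)
    if (sphere_volume(d) > rem)
      d <- max(2.2, min(14.5, (6 * rem / pi)^(1 / 3)))
    diam <- c(diam, d)
    rem <- rem - sphere_volume(d)
  }
  diam
}

place_lacunae <- function(diam) {
  # centers in mm offsets from grid center, kept apart and away from the
  # ventricles; make_lacunae_mask clips to white matter
  if (length(diam) == 0) return(NULL)
  centers <- matrix(NA_real_, length(diam), 3)
  for (i in seq_along(diam)) {
    for (try in 1:50) {
      p <- c(stats::runif(1, -14, 14), stats::runif(1, -16, 16),
             stats::runif(1, -12, 8))
      if (sqrt(sum((p / c(8, 10, 8))^2)) < 1) next  # too close to ventricles
      prev <- centers[seq_len(i - 1), , drop = FALSE]
      prev <- prev[!is.na(prev[, 1]), , drop = FALSE]
      if (nrow(prev) > 0 &&
          min(sqrt(rowSums(sweep(prev, 2, p)^2))) < diam[i] + 2) next
      centers[i, ] <- p
      break
    }
  }
  keep <- !is.na(centers[, 1])
  data.frame(x = centers[keep, 1], y = centers[keep, 2],
             z = centers[keep, 3], diameter = diam[keep])
}

group_seed <- function(seed, gi) (as.integer(seed) %% 100000L) * 10000L + gi * 1000L

#' Simulate the planted (ground-truth) cohort table
#'
#' Draws every planted per-subject quantity: zone LA loads, TICV,
#' lobe thickness (with the configured partial correlation against log
#' total LA given TICV), stroke and lacunae volumes with their caliper
#' plans, and demographic/clinical columns. Groups are generated from
#' independent seed streams, so either arm can be generated alone and is
#' unchanged by the presence of the other.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param groups Which groups to generate (default: all in the spec).
#' @return Data frame, one row per subject, with attributes
#'   `lacunae_plans` and `stroke_plans` (per-subject data frames).
#' @export
simulate_cohort <- function(spec = cohort_preset(), seed = 1L,
                            groups = names(spec$n_per_group)) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list(); lac_plans <- list(); str_plans <- list()
  for (g in groups) {
    gi <- match(g, names(spec$n_per_group))
    if (is.na(gi)) stop("unknown group: ", g)
    n <- spec$n_per_group[[g]]
    rows <- with_seed(group_seed(seed, gi), {
      zf <- sapply(c("pv", "deep", "ic"), function(zn)
        draw_lognormal_mean(n, spec$zone_means[g, zn], spec$zone_cv,
                            spec$empirical))
      zf <- pmin(matrix(zf, nrow = n, dimnames = list(NULL, c("pv", "deep", "ic"))), 95)
      ticv <- stats::rnorm(n, spec$ticv[g, "mean"], spec$ticv[g, "sd"])
      if (spec$empirical)
        ticv <- rescale_moments(ticv, spec$ticv[g, "mean"], spec$ticv[g, "sd"])
      total <- as.numeric(zf %*% REF_ZONE_SHARES[c("pv", "deep", "ic")])
      pres_s <- stats::runif(n) < spec$stroke$presence[[g]]
      pres_l <- stats::runif(n) < spec$lacunae$presence[[g]]
      stroke_d1 <- ifelse(pres_s, stats::rlnorm(n, spec$stroke$meanlog,
                                                spec$stroke$sdlog), 0)
      stroke_d2 <- stroke_d1 * stats::runif(n, 0.7, 1.1)
      stroke_ns <- ifelse(pres_s, round(stats::runif(n, 8, 25)), 0)
      stroke_ml <- stroke_volume(stroke_d1, stroke_d2, stroke_ns, 1)
      lac_ml <- ifelse(pres_l, stats::rlnorm(n, spec$lacunae$meanlog,
                                             spec$lacunae$sdlog), 0)
      lacp <- lapply(seq_len(n), function(i) {
        if (!pres_l[i]) return(NULL)
        place_lacunae(decompose_lacunae(lac_ml[i] * 1000))
      })
      # planted volume = analytic sum over the placed spheres
      lac_ml <- vapply(lacp, function(p)
        if (is.null(p)) 0 else sum(sphere_volume(p$diameter)) / 1000,
        numeric(1))
      clin <- lapply(spec$clinical[c("age", "education", "moca", "wtar",
                                     "charlson")], function(m) {
        x <- stats::rnorm(n, m[g, 1], m[g, 2])
        if (spec$empirical) x <- rescale_moments(x, m[g, 1], m[g, 2])
        x
      })
      n_male <- round(n * spec$clinical$sex_mf[g, 1] /
                        sum(spec$clinical$sex_mf[g, ]))
      sex <- sample(rep(c("M", "F"), c(n_male, n - n_male)))
      list(df = data.frame(
        id = sprintf("%s-%02d", gsub("[^A-Za-z]", "", g), seq_len(n)),
        group = g,
        planted_pv = zf[, "pv"], planted_deep = zf[, "deep"],
        planted_ic = zf[, "ic"], planted_total = total,
        ticv_mm3 = ticv,
        stroke_d1 = stroke_d1, stroke_d2 = stroke_d2,
        stroke_n_slices = stroke_ns,
        stroke_volume_mL = stroke_ml,
        planted_lacunae_mL = lac_ml,
        age = clin$age, education = clin$education, sex = sex,
        moca = clin$moca, wtar = clin$wtar, charlson = clin$charlson,
        stringsAsFactors = FALSE),
        lacp = lacp)
    })
    out[[g]] <- rows$df
    lac_plans <- c(lac_plans, rows$lacp)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  # lobe thickness is planted over the whole requested sample: the study's
  # thickness-LA partial correlation is a whole-sample quantity, so the
  # planted correlation must hold across groups, not within each arm
  th <- with_seed(group_seed(seed, 99L), {
    v <- log(tab$planted_total + 1)
    z_std <- as.numeric(scale(tab$ticv_mm3))
    sapply(names(spec$thickness$means), function(l) {
      resid <- plant_partial(v, tab$ticv_mm3,
                             spec$thickness$partial_r[[l]], nrow(tab))
      spec$thickness$means[[l]] + spec$thickness$sds[[l]] *
        (resid + spec$thickness$ticv_beta * z_std)
    })
  })
  for (l in colnames(th)) tab[[paste0("thickness_", l)]] <- th[, l]
  attr(tab, "lacunae_plans") <- lac_plans
  tab
}
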