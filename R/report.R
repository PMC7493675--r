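# Cohort-level statistical report: group comparisons, the 2x3 depth
# ANCOVA, the 2x2 anterior/posterior ANCOVA, and TICV-adjusted partial
# correlations between lobe thickness and LA load.

sr_row <- function(variable, test, s) {
  data.frame(variable = variable, test = test, statistic = s$value,
             df1 = s$df[1], df2 = if (length(s$df) > 1) s$df[2] else NA,
             p = s$p,
             effect_size = if (is.null(s$effect_size)) NA else s$effect_size,
             stringsAsFactors = FALSE)
}

#' Full statistical battery on a cohort table
#'
#' Reproduces the study's analysis plan on a measured (or planted) cohort
#' table with two groups: per-variable group comparisons (t, chi-square,
#' or Mann-Whitney U according to the declared variable type, with raw-
#' moment t's for the volume table and log-screened t's for the LA
#' battery), the group x depth (3-level) mixed ANCOVA covarying TICV, the
#' group x anterior/posterior (2-level) mixed ANCOVA, and the four
#' lobe-thickness partial correlations with log total LA controlling TICV.
#'
#' @param table Cohort data frame (from [run_cohort()]'s `$table` or
#'   [simulate_cohort()]).
#' @param alpha Significance level recorded in the report.
#' @param log_offset Offset for `log(x + offset)` transforms.
#' @param welch Use Welch instead of pooled t.
#' @return An `la_report` object.
#' @export
analysis_report <- function(table, alpha = 0.05, log_offset = 1,
                            welch = FALSE) {
  groups <- unique(table$group)
  if (length(groups) != 2)
    stop("analysis_report requires exactly two groups, got ",
         length(groups))
  g1 <- table$group == groups[1]
  pooled <- !welch
  tt <- function(v) two_sample_t(x = table[[v]][g1], y = table[[v]][!g1],
                                 pooled = pooled)
  uu <- function(v) mann_whitney_u(table[[v]][g1], table[[v]][!g1])
  lt <- function(v) two_sample_t(
    x = log_screen(table[[v]][g1], log_offset)$values,
    y = log_screen(table[[v]][!g1], log_offset)$values, pooled = pooled)

  rows <- list()
  if ("sex" %in% names(table))
    rows$sex <- sr_row("sex", "x2",
                       chi_square_counts(table(table$sex, table$group)))
  for (v in intersect(c("age", "education", "wtar", "ticv_mm3",
                        "wm_volume_mm3"), names(table)))
    rows[[v]] <- sr_row(v, "t", tt(v))
  for (v in intersect(c("moca", "charlson"), names(table)))
    rows[[v]] <- sr_row(v, "U", uu(v))
  for (v in intersect(c("la_volume_mm3", "stroke_volume_mL",
                        "lacunae_volume_mL"), names(table)))
    rows[[v]] <- sr_row(v, "t", tt(v))
  for (v in intersect(c("total_pct", "stroke_volume_mL",
                        "lacunae_volume_mL"), names(table)))
    rows[[paste0("log_", v)]] <- sr_row(paste0("log_", v), "t", lt(v))
  group_tests <- do.call(rbind, rows)
  rownames(group_tests) <- NULL

  long3 <- make_long(table, c(pv = "pv_pct", deep = "deep_pct",
                              ic = "ic_pct"), log_offset)
  depth <- mixed_ancova(long3)
  long2 <- make_long(table, c(anterior = "anterior_pct",
                              posterior = "posterior_pct"), log_offset)
  ap <- mixed_ancova(long2)

  v <- log(table$total_pct + log_offset)
  pc <- do.call(rbind, lapply(
    c("frontal", "parietal", "temporal", "occipital"), function(l) {
      col <- paste0("thickness_", l)
      if (!col %in% names(table)) return(NULL)
      sr_row(paste0(l, "_thickness~log_total"), "r",
             partial_correlation(table[[col]], v, table$ticv_mm3))
    }))
  rownames(pc) <- NULL

  structure(list(group_tests = group_tests, depth_ancova = depth,
                 ap_ancova = ap, partial_correlations = pc,
                 groups = groups, n = as.vector(table(table$group)[groups]),
                 alpha = alpha, log_offset = log_offset, welch = welch),
            class = "la_report")
}

make_long <- function(table, cols, log_offset) {
  do.call(rbind, lapply(names(cols), function(lv)
    data.frame(subject = table$id, group = table$group, within = lv,
               value = log(table[[cols[[lv]]]] + log_offset),
               covariate = table$ticv_mm3, stringsAsFactors = FALSE)))
}

#' @export
print.la_report <- function(x, ...) {
  cat(sprintf("LA cohort analysis: %s (n = %d) vs %s (n = %d), alpha = %g\n",
              x$groups[1], x$n[1], x$groups[2], x$n[2], x$alpha))
  cat("\nGroup comparisons:\n")
  gt <- x$group_tests
  gt$statistic <- signif(gt$statistic, 4)
  gt$p <- signif(gt$p, 3)
  gt$effect_size <- signif(gt$effect_size, 3)
  print(gt[, c("variable", "test", "statistic", "p")], row.names = FALSE)
  cat("\nDepth (PV/deep/IC) mixed ANCOVA, TICV covaried:\n")
  print(x$depth_ancova)
  cat("\nAnterior/posterior mixed ANCOVA, TICV covaried:\n")
  print(x$ap_ancova)
  cat("\nPartial correlations (controlling TICV):\n")
  pc <- x$partial_correlations
  pc$statistic <- signif(pc$statistic, 4)
  pc$p <- signif(pc$p, 3)
  print(pc[, c("variable", "statistic", "df1", "p")], row.names = FALSE)
  invisible(x)
}

#' Convert a report to a plain list for JSON serialization
#' @param x An `la_report`.
#' @return Nested list of plain vectors.
#' @export
report_as_list <- function(x) {
  stopifnot(inherits(x, "la_report"))
  anc <- function(a) lapply(a$effects, function(e)
    list(F = e$value, df = e$df, p = e$p, partial_eta_sq = e$effect_size))
  list(groups = x$groups, n = x$n, alpha = x$alpha,
       group_tests = x$group_tests,
       depth_ancova = anc(x$depth_ancova),
       ap_ancova = anc(x$ap_ancova),
       partial_correlations = x$partial_correlations)
}
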