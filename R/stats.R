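# Statistical battery: log screening, two-sample tests, mixed-design
# ANCOVA with partial eta squared, and covariate-adjusted partial
# correlations.

stat_result <- function(statistic, value, df, p, effect_size = NULL,
                        effect_name = NULL, note = NULL) {
  structure(list(statistic = statistic, value = value, df = df, p = p,
                 effect_size = effect_size, effect_name = effect_name,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s(%s) = %.4g, p = %.4g", x$statistic, dfs, x$value, x$p))
  if (!is.null(x$effect_size))
    cat(sprintf(", %s = %.3f", x$effect_name, x$effect_size))
  if (!is.null(x$note)) cat("  [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

sample_skewness <- function(x) {
  # adjusted Fisher-Pearson coefficient (the SPSS/Excel convention)
  n <- length(x); m <- mean(x); s <- stats::sd(x)
  n / ((n - 1) * (n - 2)) * sum(((x - m) / s)^3)
}

sample_kurtosis <- function(x) {
  # excess kurtosis, SPSS convention
  n <- length(x); m <- mean(x); s <- stats::sd(x)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - m) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Log-transform screening of a skewed variable
#'
#' Applies `log(x + offset)` (natural log; the default offset of 1 admits
#' zeros) and reports the sample skewness and excess kurtosis of the
#' transformed values, flagging whether both lie within \[-1, 1\].
#'
#' @param values Non-negative numeric vector.
#' @param offset Offset added before the log (default 1).
#' @return List: `values` (transformed), `skewness`, `kurtosis`,
#'   `within_unit` (logical), `offset`.
#' @export
log_screen <- function(values, offset = 1) {
  if (any(values < 0)) stop("log_screen requires non-negative values")
  y <- log(values + offset)
  sk <- sample_skewness(y)
  ku <- sample_kurtosis(y)
  list(values = y, skewness = sk, kurtosis = ku,
       within_unit = is.finite(sk) && is.finite(ku) &&
         abs(sk) <= 1 && abs(ku) <= 1,
       offset = offset)
}

#' Independent-samples t-test from raw vectors or summary statistics
#'
#' Pooled-variance t by default (`df = n1 + n2 - 2`), Welch when
#' `pooled = FALSE`. Accepts either two raw vectors or the six summary
#' moments; both paths reduce to the same moment formula, so a t computed
#' from a table's printed means and SDs is exactly the raw-data t.
#'
#' @param x,y Raw samples (alternative to the summary interface).
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs, and sizes.
#' @param pooled Pooled-variance (default) vs Welch.
#' @return A `stat_result` with `statistic = "t"`.
#' @export
two_sample_t <- function(x = NULL, y = NULL, m1 = NULL, s1 = NULL, n1 = NULL,
                         m2 = NULL, s2 = NULL, n2 = NULL, pooled = TRUE) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("supply both raw vectors")
    m1 <- mean(x); s1 <- stats::sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- stats::sd(y); n2 <- length(y)
  }
  if (any(vapply(list(m1, s1, n1, m2, s2, n2), is.null, logical(1))))
    stop("supply raw vectors or all six summary statistics")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(stat_result("t", 0, n1 + n2 - 2, 1,
                         note = "zero variance in both groups, equal means"))
    stop("zero variance in both groups with unequal means")
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  stat_result("t", t, df, 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' Without continuity correction, df = 1.
#'
#' @param contingency 2x2 matrix of non-negative counts.
#' @return A `stat_result` with `statistic = "x2"`.
#' @export
chi_square_counts <- function(contingency) {
  tab <- as.matrix(contingency)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total; the chi-square statistic is undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("x2", unname(res$statistic), unname(res$parameter),
              unname(res$p.value))
}

#' Mann-Whitney U test
#'
#' Rank-sum U for the first sample (`U = #\{x > y\} + ties/2`) with the
#' tie-corrected normal approximation for p.
#'
#' @param x,y Numeric vectors.
#' @return A `stat_result` with `statistic = "U"`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  stat_result("U", unname(res$statistic), NA_real_, unname(res$p.value))
}

rss_fit <- function(X, y) sum(qr.resid(qr(X), y)^2)

#' Mixed-design (split-plot) ANCOVA with a between-subject covariate
#'
#' Two-group by k-level repeated-measures ANOVA with a subject-constant
#' covariate, the convention used by mainstream repeated-measures GLM
#' software: the covariate enters both strata, so the between-subject
#' error has `N - 3` df and the within-subject error `(k - 1)(N - 3)` df.
#' Sphericity is assumed (no correction). Effect sizes are partial eta
#' squared, `SS_effect / (SS_effect + SS_error)`; sums of squares are
#' partial (Type III, sum-to-zero contrasts).
#'
#' @param data Long-format data frame.
#' @param value,subject,group,within,covariate Column names.
#' @return A `mixed_ancova` object: list of `stat_result`s for `within`
#'   (the within-factor main effect), `interaction` (group x factor),
#'   `group` (between), and `covariate`, plus the SS table.
#' @export
mixed_ancova <- function(data, value = "value", subject = "subject",
                         group = "group", within = "within",
                         covariate = "covariate") {
  y <- data[[value]]
  S <- factor(data[[subject]])
  G <- factor(data[[group]])
  W <- factor(data[[within]])
  Z <- data[[covariate]]
  if (any(is.na(y)) || any(is.na(Z))) stop("missing values are not supported")
  k <- nlevels(W); N <- nlevels(S); ng <- nlevels(G)
  tab <- table(S, W)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    stop("unbalanced within-factor design; offending subject(s): ",
         paste(bad, collapse = ", "))
  }
  per_sub <- function(v) tapply(v, S, function(u) u[1])
  if (any(tapply(Z, S, function(u) length(unique(u))) != 1L))
    stop("covariate must be constant within subject")
  if (any(tapply(as.integer(G), S, function(u) length(unique(u))) != 1L))
    stop("group must be constant within subject")

  ## between stratum: subject means ~ covariate + group
  M <- as.numeric(tapply(y, S, mean))
  Zs <- as.numeric(per_sub(Z))
  Gs <- factor(as.character(per_sub(as.character(G))))
  Xg <- stats::model.matrix(~ Gs, contrasts.arg = list(Gs = "contr.sum"))
  X_full_b <- cbind(Xg, Zs)
  ss_err_b <- rss_fit(X_full_b, M) * k
  ss_group <- (rss_fit(cbind(1, Zs), M) - rss_fit(X_full_b, M)) * k
  ss_cov <- (rss_fit(Xg, M) - rss_fit(X_full_b, M)) * k
  df_err_b <- N - ng - 1
  F_g <- (ss_group / (ng - 1)) / (ss_err_b / df_err_b)
  F_z <- ss_cov / (ss_err_b / df_err_b)

  ## within stratum: y ~ subject + W + W:G + W:Z, Type III drop-term SS
  Cw <- stats::contr.sum(k)[W, , drop = FALSE]
  Cg <- stats::contr.sum(ng)[G, , drop = FALSE]
  Xs <- stats::model.matrix(~ 0 + S)
  Xw <- Cw
  Xwg <- do.call(cbind, lapply(seq_len(ncol(Cg)), function(j) Cw * Cg[, j]))
  Xwz <- Cw * Z
  X_full <- cbind(Xs, Xw, Xwg, Xwz)
  rss_full <- rss_fit(X_full, y)
  ss_w  <- rss_fit(cbind(Xs, Xwg, Xwz), y) - rss_full
  ss_wg <- rss_fit(cbind(Xs, Xw, Xwz), y) - rss_full
  df_err_w <- (k - 1) * (N - ng - 1)
  df_w <- k - 1
  df_wg <- (k - 1) * (ng - 1)
  F_w <- (ss_w / df_w) / (rss_full / df_err_w)
  F_wg <- (ss_wg / df_wg) / (rss_full / df_err_w)

  pes <- function(ss, ss_err) ss / (ss + ss_err)
  eff <- list(
    within = stat_result("F", F_w, c(df_w, df_err_w),
                         stats::pf(F_w, df_w, df_err_w, lower.tail = FALSE),
                         pes(ss_w, rss_full), "partial_eta_sq"),
    interaction = stat_result("F", F_wg, c(df_wg, df_err_w),
                              stats::pf(F_wg, df_wg, df_err_w,
                                        lower.tail = FALSE),
                              pes(ss_wg, rss_full), "partial_eta_sq"),
    group = stat_result("F", F_g, c(ng - 1, df_err_b),
                        stats::pf(F_g, ng - 1, df_err_b, lower.tail = FALSE),
                        pes(ss_group, ss_err_b), "partial_eta_sq"),
    covariate = stat_result("F", F_z, c(1, df_err_b),
                            stats::pf(F_z, 1, df_err_b, lower.tail = FALSE),
                            pes(ss_cov, ss_err_b), "partial_eta_sq")
  )
  structure(list(effects = eff,
                 ss = c(within = ss_w, interaction = ss_wg,
                        error_within = rss_full, group = ss_group,
                        covariate = ss_cov, error_between = ss_err_b),
                 df = c(within = df_w, interaction = df_wg,
                        error_within = df_err_w, group = ng - 1,
                        covariate = 1, error_between = df_err_b),
                 n_subjects = N, n_levels = k),
            class = "mixed_ancova")
}

#' @export
print.mixed_ancova <- function(x, ...) {
  cat(sprintf("Mixed-design ANCOVA: %d subjects x %d levels\n",
              x$n_subjects, x$n_levels))
  for (nm in names(x$effects)) {
    cat(sprintf("  %-12s ", nm)); print(x$effects[[nm]])
  }
  invisible(x)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing
#' each on `z`; p from the t transform with `n - 3` df.
#'
#' @param x,y,z Numeric vectors of equal length, n >= 4.
#' @return A `stat_result` with `statistic = "r"`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("partial correlation requires n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("constant input; correlation undefined")
  ex <- stats::lm.fit(cbind(1, z), x)$residuals
  ey <- stats::lm.fit(cbind(1, z), y)$residuals
  r <- stats::cor(ex, ey)
  df <- n - 3
  t <- r * sqrt(df / (1 - r^2))
  stat_result("r", r, df, 2 * stats::pt(-abs(t), df), effect_size = r,
              effect_name = "r")
}
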