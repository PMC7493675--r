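# Statistical battery: transforms, group tests, mixed ANCOVA, partial
# correlations.

moment_vector <- function(n, m, s, seed) {
  # vector with exactly the requested sample mean and SD
  set.seed(seed)
  x <- rnorm(n)
  as.numeric(m + s * (x - mean(x)) / sd(x))
}

test_that("log_screen transforms, screens, and validates", {
  z <- log_screen(rep(0, 10))
  expect_equal(z$values, rep(0, 10))
  x <- sort(runif(20, 0, 50))
  expect_equal(order(log_screen(x)$values), 1:20)  # monotone
  expect_error(log_screen(c(-1, 2)), "non-negative")
})

test_that("log transform brings a log-normal sample inside |skew| <= 1", {
  set.seed(21)
  x <- rlnorm(200, 1, 0.9)
  raw_skew <- oracle_skewness(x)
  expect_gt(raw_skew, 1)
  scr <- log_screen(x, offset = 0.001)
  expect_true(scr$within_unit)
  expect_equal(scr$skewness, oracle_skewness(log(x + 0.001)),
               tolerance = 1e-12)
})

test_that("summary-statistic t equals the raw-vector t to 10 digits", {
  x <- moment_vector(17, 8507.7, 8445.2, 31)
  y <- moment_vector(17, 3985.8, 4707.1, 32)
  t_raw <- two_sample_t(x, y)
  t_sum <- two_sample_t(m1 = 8507.7, s1 = 8445.2, n1 = 17,
                        m2 = 3985.8, s2 = 4707.1, n2 = 17)
  expect_equal(t_raw$value, t_sum$value, tolerance = 1e-10)
  expect_equal(t_raw$df, t_sum$df)
  expect_equal(t_raw$p, t_sum$p, tolerance = 1e-10)
  # and both agree with stats::t.test
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(t_raw$value, unname(tt$statistic), tolerance = 1e-10)
})

test_that("t-test conventions: zero variance, Welch, validation", {
  expect_equal(two_sample_t(m1 = 5, s1 = 0, n1 = 8, m2 = 5, s2 = 0,
                            n2 = 8)$value, 0)
  expect_error(two_sample_t(m1 = 5, s1 = 0, n1 = 8, m2 = 6, s2 = 0, n2 = 8),
               "zero variance")
  expect_error(two_sample_t(m1 = 1, s1 = 1, n1 = 1, m2 = 0, s2 = 1, n2 = 9),
               "n >= 2")
  w <- two_sample_t(m1 = 10, s1 = 8, n1 = 12, m2 = 7, s2 = 2, n2 = 20,
                    pooled = FALSE)
  x <- moment_vector(12, 10, 8, 33); y <- moment_vector(20, 7, 2, 34)
  tw <- t.test(x, y)
  expect_equal(w$value, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-8)
})

test_that("chi-square matches the hand-computed expected-count oracle", {
  expect_equal(chi_square_counts(rbind(c(11, 6), c(11, 6)))$value, 0)
  tab <- rbind(c(10, 5), c(3, 12))
  # oracle: direct sum of (O - E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_counts(tab)$value, sum((tab - E)^2 / E),
               tolerance = 1e-12)
  expect_error(chi_square_counts(rbind(c(0, 0), c(3, 4))), "marginal")
  expect_error(chi_square_counts(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("Mann-Whitney U equals the brute-force pairwise count", {
  x <- c(3, 3, 5, 9); y <- c(3, 4, 7, 8)
  brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(mann_whitney_u(x, y)$value, brute)
  set.seed(41)
  for (i in 1:5) {
    a <- sample(1:8, 12, replace = TRUE)
    b <- sample(1:8, 9, replace = TRUE)
    brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney_u(a, b)$value, brute)
  }
  v <- c(1, 2, 3, 4, 5)
  expect_equal(mann_whitney_u(v, v)$value, length(v)^2 / 2)
  expect_equal(mann_whitney_u(1:4, 11:14)$value, 0)
})

test_that("partial correlation equals the closed-form identity", {
  set.seed(51)
  for (i in 1:5) {
    n <- 30
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + 0.4 * x + rnorm(n)
    got <- partial_correlation(x, y, z)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    want <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(got$value, want, tolerance = 1e-10)
    expect_equal(got$df, n - 3)
  }
})

test_that("partial correlation edge behavior", {
  set.seed(52)
  x <- rnorm(20); z <- rnorm(20)
  expect_gt(partial_correlation(x, x, z)$value, 0.999999)
  expect_error(partial_correlation(x[1:3], x[1:3], z[1:3]), "n >= 4")
  expect_error(partial_correlation(rep(1, 10), rnorm(10), rnorm(10)),
               "constant")
})

make_long_cohort <- function(n_per_group, k, seed, group_shift = 0,
                             region_effect = rep(0, k),
                             interaction = 0) {
  set.seed(seed)
  N <- 2 * n_per_group
  g <- rep(c("A", "B"), each = n_per_group)
  z <- rnorm(N, 100, 10)
  subj_int <- rnorm(N, 0, 1.5) + ifelse(g == "A", group_shift, 0) + 0.02 * z
  do.call(rbind, lapply(1:k, function(lv)
    data.frame(subject = sprintf("s%02d", 1:N), group = g,
               within = paste0("L", lv),
               value = subj_int + region_effect[lv] +
                 ifelse(g == "A", interaction * (lv - (k + 1) / 2), 0) +
                 rnorm(N),
               covariate = z)))
}

test_that("mixed ANCOVA df structure matches the repeated-measures GLM", {
  d <- make_long_cohort(17, 3, seed = 61, region_effect = c(1, 0, -1))
  fit <- mixed_ancova(d)
  expect_equal(fit$effects$within$df, c(2, 62))
  expect_equal(fit$effects$interaction$df, c(2, 62))
  expect_equal(fit$effects$group$df, c(1, 31))
  d2 <- make_long_cohort(17, 2, seed = 62)
  fit2 <- mixed_ancova(d2)
  expect_equal(fit2$effects$within$df, c(1, 31))
})

test_that("ANCOVA sums of squares match an independent projection oracle", {
  d <- make_long_cohort(4, 3, seed = 63, group_shift = 2,
                        region_effect = c(1, 0, -1), interaction = 0.8)
  fit <- mixed_ancova(d)
  # oracle: explicit projection matrices over sum-coded design blocks
  y <- d$value
  S <- factor(d$subject); W <- factor(d$within); G <- factor(d$group)
  Z <- d$covariate
  Cw <- contr.sum(3)[W, , drop = FALSE]
  Cg <- contr.sum(2)[G, , drop = FALSE]
  Xs <- model.matrix(~ 0 + S)
  Xwg <- Cw * Cg[, 1]
  Xwz <- Cw * Z
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  rss <- function(X) { P <- proj(X); sum((y - P %*% y)^2) }
  full <- cbind(Xs, Cw, Xwg, Xwz)
  expect_equal(unname(fit$ss[["within"]]),
               rss(cbind(Xs, Xwg, Xwz)) - rss(full), tolerance = 1e-8)
  expect_equal(unname(fit$ss[["interaction"]]),
               rss(cbind(Xs, Cw, Xwz)) - rss(full), tolerance = 1e-8)
  expect_equal(unname(fit$ss[["error_within"]]), rss(full), tolerance = 1e-8)
  # between stratum, on subject means (scaled by k)
  M <- as.numeric(tapply(y, S, mean))
  Zs <- as.numeric(tapply(Z, S, function(u) u[1]))
  Gs <- factor(tapply(as.character(G), S, function(u) u[1]))
  Xg <- model.matrix(~ Gs, contrasts.arg = list(Gs = "contr.sum"))
  yM <- M
  rssM <- function(X) { P <- X %*% solve(crossprod(X), t(X)); sum((yM - P %*% yM)^2) }
  expect_equal(unname(fit$ss[["group"]]),
               3 * (rssM(cbind(1, Zs)) - rssM(cbind(Xg, Zs))),
               tolerance = 1e-8)
})

test_that("partial eta squared is bounded and grows with the planted effect", {
  pes <- vapply(c(0, 0.6, 1.2), function(eff) {
    d <- make_long_cohort(10, 3, seed = 64, interaction = eff)
    fit <- mixed_ancova(d)
    for (e in fit$effects) {
      expect_gte(e$effect_size, 0); expect_lte(e$effect_size, 1)
    }
    fit$effects$interaction$effect_size
  }, numeric(1))
  expect_true(all(diff(pes) > 0))
})

test_that("unbalanced designs are rejected with the offending subject named", {
  d <- make_long_cohort(4, 3, seed = 65)
  d <- d[-1, ]  # s01 loses one level
  expect_error(mixed_ancova(d), "s01")
  d2 <- make_long_cohort(4, 3, seed = 66)
  d2$covariate[1] <- d2$covariate[1] + 5
  expect_error(mixed_ancova(d2), "covariate")
})
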