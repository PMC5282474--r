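test_that("ANOVA with Tukey: degenerate and two-group identities", {
  set.seed(40)
  v <- rnorm(6)
  # the same sample observed in every group: zero between-group variance
  at <- anova_tukey(rep(v, 3), rep(1:3, each = 6))
  expect_equal(at$F, 0, tolerance = 1e-12)
  expect_equal(at$p, 1, tolerance = 1e-12)
  expect_true(all(at$tukey$p_adj > 0.999))

  # with two groups, Tukey reduces to the pooled two-sample t-test
  x <- rnorm(8); y <- rnorm(8, 0.7)
  at2 <- anova_tukey(c(x, y), rep(1:2, each = 8))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(at2$tukey$p_adj, tt$p.value, tolerance = 1e-8)
  expect_equal(at2$p, tt$p.value, tolerance = 1e-8)

  expect_error(anova_tukey(1:5, c(1, 1, 1, 1, 2)), "singleton")
})

test_that("ANOVA omnibus holds its nominal type-I error under the null", {
  set.seed(41)
  rej <- vapply(1:2000, function(i) {
    anova_tukey(rnorm(18), rep(1:3, each = 6))$p < 0.05
  }, logical(1))
  # 3 * binomial SE at 2000 replicates is about 0.015
  expect_gt(mean(rej), 0.032)
  expect_lt(mean(rej), 0.068)
})

test_that("Tukey-adjusted p-values are never smaller than unadjusted pairwise t-tests", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- rnorm(24, mean = rep(c(0, 0.5, 1, 0.2), each = 6))
    grp <- factor(rep(1:4, each = 6))
    at <- anova_tukey(vals, grp)
    fit <- aov(vals ~ grp)
    mse <- sum(fit$residuals^2) / fit$df.residual
    for (i in seq_len(nrow(at$tukey))) {
      ab <- strsplit(at$tukey$contrast[i], "-")[[1]]
      va <- vals[grp == ab[1]]; vb <- vals[grp == ab[2]]
      tstat <- (mean(va) - mean(vb)) /
        sqrt(mse * (1 / length(va) + 1 / length(vb)))
      p_unadj <- 2 * pt(abs(tstat), fit$df.residual, lower.tail = FALSE)
      expect_gte(at$tukey$p_adj[i] + 1e-12, p_unadj)
    }
  }
})

test_that("Lilliefors normality check behaves under normal and lognormal sampling", {
  set.seed(43)
  p_norm <- vapply(1:200, function(i) ks_normality(rnorm(30)), numeric(1))
  expect_lt(mean(p_norm < 0.05), 0.12)      # near-nominal rejection
  expect_gt(mean(p_norm), 0.35)             # roughly uniform p-values
  expect_lt(mean(p_norm), 0.65)
  p_logn <- vapply(1:100, function(i)
    ks_normality(exp(rnorm(50, sd = 1.2))), numeric(1))
  expect_gt(mean(p_logn < 0.05), 0.5)       # strong rejection
  expect_error(ks_normality(rep(3, 10)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
})

test_that("Pearson correlation: exact lines and recovery of rho = 0.9", {
  x <- seq_len(10)
  expect_equal(pearson(x, 2 * x + 1)$R, 1)
  expect_equal(pearson(x, -x)$R, -1)
  expect_error(pearson(x, rep(1, 10)), "variance")

  set.seed(44)
  rs <- vapply(1:1000, function(i) {
    z <- rnorm(25); e <- rnorm(25)
    y <- 0.9 * z + sqrt(1 - 0.81) * e
    pearson(z, y)$R
  }, numeric(1))
  # mean estimate near rho with the known small negative bias
  expect_gt(mean(rs), 0.875)
  expect_lt(mean(rs), 0.915)
})

test_that("standardized regression recovers exact and orthogonal cases", {
  d <- data.frame(x = rnorm(20))
  d$y <- 2 * d$x
  fr <- suppressWarnings(fit_regression(d, "y", "x"))  # perfect-fit warning
  expect_equal(unname(fr$beta), 1, tolerance = 1e-12)
  expect_equal(fr$r_squared, 1, tolerance = 1e-12)
  # single standardized predictor: beta^2 = R^2
  set.seed(45)
  d2 <- data.frame(x = rnorm(40)); d2$y <- 0.5 * d2$x + rnorm(40)
  fr2 <- fit_regression(d2, "y", "x")
  expect_equal(unname(fr2$beta)^2, fr2$r_squared, tolerance = 1e-10)
  expect_equal(fr2$r_squared, pearson(d2$x, d2$y)$R^2, tolerance = 1e-10)

  d3 <- data.frame(x = rnorm(2000)); d3$y <- rnorm(2000)
  expect_lt(abs(unname(fit_regression(d3, "y", "x")$beta)), 0.06)

  d4 <- data.frame(x = rnorm(10)); d4$x2 <- d4$x; d4$y <- rnorm(10)
  expect_error(fit_regression(d4, "y", c("x", "x2")), "collinear")
})

test_that("pooled SD matches the closed form and a concatenation oracle", {
  expect_equal(pooled_sd(1.7, 5, 1.7, 9), 1.7)
  expect_equal(pooled_sd(0, 4, 2, 4), sqrt(2))
  set.seed(46)
  a <- rnorm(7, 5, 2); b <- rnorm(12, -1, 0.5)
  # pooled SD = SD of the two mean-centered groups concatenated (with the
  # matching df convention)
  centered <- c(a - mean(a), b - mean(b))
  oracle <- sqrt(sum(centered^2) / (length(a) + length(b) - 2))
  expect_equal(pooled_sd(sd(a), 7, sd(b), 12), oracle, tolerance = 1e-12)
  expect_error(pooled_sd(1, 1, 1, 4), ">= 2")
})

test_that("standardized differences use the wild-type linear-aging interpolation", {
  tg <- data.frame(age_months = c(5, 8, 13, 16), mean = 10, sd = 2, n = 8)
  wt <- data.frame(age_months = c(5, 16), mean = c(6, 6))
  s <- standardized_difference_series(tg, wt)
  expect_equal(s$d, rep(2, 4))

  # midpoint of the line through (6 mo, 4) and (18 mo, 8) is 6 at 12 mo
  tg2 <- data.frame(age_months = 12, mean = 7, sd = 0.5, n = 8)
  wt2 <- data.frame(age_months = c(6, 18), mean = c(4, 8))
  s2 <- standardized_difference_series(tg2, wt2)
  expect_equal(s2$wt_interp, 6)
  expect_equal(s2$d, 2)
  # extrapolation below the first wild-type age follows the same line
  s2b <- standardized_difference_series(
    data.frame(age_months = 3, mean = 4, sd = 1, n = 8), wt2)
  expect_equal(s2b$wt_interp, 3)

  # invariance under a change of measurement units
  set.seed(47)
  tg3 <- data.frame(age_months = c(5, 8, 13, 16),
                    mean = runif(4, 5, 30), sd = runif(4, 1, 4), n = 8)
  wt3 <- data.frame(age_months = c(5, 16), mean = c(4, 9))
  s3 <- standardized_difference_series(tg3, wt3)
  tg3s <- tg3; tg3s$mean <- tg3$mean * 37; tg3s$sd <- tg3$sd * 37
  wt3s <- wt3; wt3s$mean <- wt3$mean * 37
  expect_equal(standardized_difference_series(tg3s, wt3s)$d, s3$d,
               tolerance = 1e-12)

  # spreadsheet-style recomputation oracle
  slope <- (wt3$mean[2] - wt3$mean[1]) / (16 - 5)
  for (i in 1:4) {
    wi <- wt3$mean[1] + slope * (tg3$age_months[i] - 5)
    expect_equal(s3$d[i], (tg3$mean[i] - wi) / tg3$sd[i], tolerance = 1e-12)
  }

  # pooled-SD rule for two adjacent distorted ages
  tg4 <- data.frame(age_months = c(5, 8), mean = c(10, 12),
                    sd = c(0, 2), n = c(8, 8))
  expect_error(standardized_difference_series(tg4, wt3), "zero SD")
  s4 <- standardized_difference_series(tg4, wt3, pool_ages = c(5, 8))
  expect_equal(s4$sd_used, rep(pooled_sd(0, 8, 2, 8), 2))
})

test_that("group size planning matches a simulation oracle and is monotone", {
  n <- group_size(0.05, 0.8, effect_size_d = 2)
  sim_power <- function(nn, d, reps = 6000) {
    set.seed(48)
    mean(vapply(seq_len(reps), function(i) {
      t.test(rnorm(nn, d), rnorm(nn), var.equal = TRUE)$p.value < 0.05
    }, logical(1)))
  }
  expect_gte(sim_power(n, 2), 0.8 - 0.02)
  expect_lt(sim_power(n - 1, 2), 0.8 + 0.02)

  # enormous effects need only the minimum sensible group
  expect_equal(group_size(0.05, 0.8, effect_size_d = 50), 2L)
  # n is nonincreasing in d
  ns <- vapply(c(0.3, 0.5, 1, 2, 5), function(d)
    group_size(0.05, 0.8, d), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(group_size(0.05, 0.8, -1), "effect size")
})
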