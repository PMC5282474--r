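#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus F test across groups (typically age groups within one genotype)
#' followed by Tukey studentized-range pairwise comparisons.
#'
#' @param values numeric vector of measurements.
#' @param group grouping factor (coerced); at least 2 groups, each n >= 2.
#' @return a list with `F`, `df1`, `df2`, `p` and `tukey`, a data frame of
#'   pairwise contrasts (contrast, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  assert_that(length(values) == length(group), "values/group length mismatch")
  counts <- table(group)
  assert_that(nlevels(group) >= 2, "need at least 2 groups")
  assert_that(all(counts >= 2), "singleton group(s): %s",
              paste(names(counts)[counts < 2], collapse = ", "))
  fit <- aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Lilliefors-type Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample, with the Lilliefors correction for the
#' estimated parameters (via [nortest::lillie.test()]). Requires n >= 5 for
#' the p-value approximation; constant samples are degenerate and an error.
#'
#' @param values numeric sample.
#' @return p-value.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  assert_that(length(values) >= 5 && all(is.finite(values)),
              "need at least 5 finite values")
  assert_that(sd(values) > 0, "constant sample: normality test degenerate")
  nortest::lillie.test(values)$p.value
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-based two-sided test.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return list with `R`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "x and y must have equal length >= 3")
  assert_that(sd(x) > 0 && sd(y) > 0, "zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardized multiple regression
#'
#' Ordinary least squares on z-scored outcome and predictors, reporting
#' standardized coefficients (beta), per-coefficient p-values, R-squared,
#' adjusted R-squared and the overall F statistic with its degrees of
#' freedom. With standardization the coefficients are dimensionless and,
#' for a single predictor, beta^2 = R^2.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names (typically
#'   including `age_months` as the covariate).
#' @param standardize z-score all variables first (default TRUE).
#' @return list with `beta` (named), `p` (named), `r_squared`,
#'   `adj_r_squared`, `F`, `df1`, `df2`, `n`.
#' @export
fit_regression <- function(data, outcome, predictors, standardize = TRUE) {
  assert_that(all(c(outcome, predictors) %in% names(data)),
              "missing columns: %s",
              paste(setdiff(c(outcome, predictors), names(data)),
                    collapse = ", "))
  d <- data[complete.cases(data[, c(outcome, predictors)]),
            c(outcome, predictors), drop = FALSE]
  n <- nrow(d)
  assert_that(n > length(predictors) + 1,
              "need n > number of predictors + 1 (n=%d, p=%d)",
              n, length(predictors))
  if (standardize) d[] <- lapply(d, function(col) as.numeric(scale(col)))
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- lm(fml, data = d)
  assert_that(fit$rank == length(predictors) + 1,
              "rank-deficient design: collinear predictors among {%s}",
              paste(predictors, collapse = ", "))
  s <- summary(fit)
  co <- s$coefficients[predictors, , drop = FALSE]
  list(beta = setNames(co[, "Estimate"], predictors),
       p = setNames(co[, "Pr(>|t|)"], predictors),
       r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
       F = unname(s$fstatistic["value"]),
       df1 = unname(s$fstatistic["numdf"]),
       df2 = unname(s$fstatistic["dendf"]), n = n)
}

#' Pooled (combined) standard deviation of two groups
#'
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))` - the combined-SD
#' approximation used when one group's own SD is unreliably small.
#'
#' @param sd1,sd2 group SDs (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @return pooled SD.
#' @export
pooled_sd <- function(sd1, n1, sd2, n2) {
  assert_that(n1 >= 2 && n2 >= 2, "group sizes must be >= 2")
  assert_that(sd1 >= 0 && sd2 >= 0, "SDs must be nonnegative")
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Standardized-difference timeline versus a linearly aging control group
#'
#' For each transgenic age a, computes `d(a) = (mean_TG(a) - wt_interp(a)) /
#' SD_TG(a)`, where `wt_interp` is the straight line through the two
#' wild-type (age, mean) points - the assumption that control measures
#' develop linearly during aging, extrapolated when a transgenic age lies
#' outside the control ages. When `pool_ages` names two adjacent transgenic
#' ages, their pooled SD (see [pooled_sd()]) replaces both groups' own SDs -
#' the combined-SD approximation for a time point with a distorted, unusably
#' small SD.
#'
#' @param tg data frame with columns `age_months`, `mean`, `sd`, `n` (one row
#'   per transgenic age).
#' @param wt data frame with columns `age_months`, `mean` - exactly two rows.
#' @param pool_ages optional numeric vector of two transgenic ages whose SDs
#'   are pooled.
#' @param measure optional measure label carried into the output.
#' @return data frame: measure, age_months, d, wt_interp, sd_used.
#' @export
standardized_difference_series <- function(tg, wt, pool_ages = NULL,
                                           measure = NA_character_) {
  assert_that(is.data.frame(tg) &&
                all(c("age_months", "mean", "sd", "n") %in% names(tg)),
              "tg must have columns age_months, mean, sd, n")
  assert_that(is.data.frame(wt) && nrow(wt) == 2 &&
                all(c("age_months", "mean") %in% names(wt)),
              "wt must have exactly two rows with columns age_months, mean")
  assert_that(wt$age_months[1] != wt$age_months[2],
              "the two wild-type ages must differ")
  slope <- (wt$mean[2] - wt$mean[1]) / (wt$age_months[2] - wt$age_months[1])
  wt_interp <- wt$mean[1] + slope * (tg$age_months - wt$age_months[1])

  sd_used <- tg$sd
  if (!is.null(pool_ages)) {
    assert_that(length(pool_ages) == 2 && all(pool_ages %in% tg$age_months),
                "pool_ages must name two transgenic ages present in tg")
    i <- match(pool_ages, tg$age_months)
    sp <- pooled_sd(tg$sd[i[1]], tg$n[i[1]], tg$sd[i[2]], tg$n[i[2]])
    sd_used[i] <- sp
  }
  assert_that(all(sd_used > 0),
              "zero SD at age(s) %s: use pool_ages to invoke the pooled-SD rule",
              paste(tg$age_months[sd_used <= 0], collapse = ", "))
  data.frame(measure = measure, age_months = tg$age_months,
             d = (tg$mean - wt_interp) / sd_used,
             wt_interp = wt_interp, sd_used = sd_used,
             stringsAsFactors = FALSE)
}

#' Group size for a two-sample t-test at given power
#'
#' Smallest per-group n such that a two-sided two-sample t-test at level
#' `alpha` reaches at least the requested power at standardized effect size
#' `d`, using the exact noncentral-t power computation of
#' [stats::power.t.test()]. The floor is n = 2 (the smallest group with a
#' defined variance).
#'
#' @param alpha type I error level in (0, 1).
#' @param power target power in (0, 1).
#' @param effect_size_d standardized effect size (Cohen's d), > 0.
#' @param n_max search ceiling (error if exceeded).
#' @return integer n per group.
#' @export
group_size <- function(alpha = 0.05, power = 0.8, effect_size_d,
                       n_max = 1e5) {
  assert_that(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must be in (0, 1)")
  assert_that(is.numeric(effect_size_d) && effect_size_d > 0,
              "effect size d must be > 0")
  pow_at <- function(n) {
    power.t.test(n = n, delta = effect_size_d, sd = 1, sig.level = alpha,
                 type = "two.sample", alternative = "two.sided")$power
  }
  # continuous solve as a starting point, then exact integer scan
  n0 <- tryCatch(ceiling(power.t.test(delta = effect_size_d, sd = 1,
                                      sig.level = alpha, power = power,
                                      type = "two.sample")$n),
                 error = function(e) 2)
  n <- max(2, n0 - 2)
  while (n <= n_max && pow_at(n) < power) n <- n + 1
  assert_that(n <= n_max, "requested power unattainable below n_max = %g",
              n_max)
  while (n > 2 && pow_at(n - 1) >= power) n <- n - 1
  as.integer(n)
}
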