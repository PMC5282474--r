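random_category_case <- function(n = 500, seed = 1) {
  set.seed(seed)
  dims <- c(n, 1, 1)
  mask <- array(TRUE, dim = dims)
  ts <- synth_binmap(array(runif(n) < 0.4, dim = dims), mask,
                     age_months = 5)
  am <- synth_binmap(array(runif(n) < 0.3, dim = dims), mask,
                     age_months = 5)
  list(ts = ts, am = am, mask = mask)
}

test_that("category codes follow the fixed four-way truth table", {
  dims <- c(4, 1, 1)
  mask <- array(TRUE, dim = dims)
  ts <- synth_binmap(array(c(TRUE, TRUE, FALSE, FALSE), dims), mask)
  am <- synth_binmap(array(c(TRUE, FALSE, TRUE, FALSE), dims), mask)
  cm <- combine_categories(ts, am, mask, age_months = 8)
  expect_equal(as.vector(cm$codes), c(3L, 1L, 2L, 0L))

  empty <- synth_binmap(array(FALSE, dims), mask)
  cm0 <- combine_categories(empty, empty, mask)
  expect_true(all(cm0$codes == 0L))
})

test_that("occupancy partitions 100% of the brain and matches a counting oracle", {
  cs <- random_category_case(seed = 21)
  cm <- combine_categories(cs$ts, cs$am, cs$mask)
  occ <- occupancy(cm)
  expect_equal(occ$pct_neither + occ$pct_tspo_only + occ$pct_amyloid_only +
                 occ$pct_both, 100, tolerance = 1e-9)
  # brute-force counts
  codes <- cm$codes[cs$mask]
  for (k in 0:3) {
    col <- c("pct_neither", "pct_tspo_only", "pct_amyloid_only",
             "pct_both")[k + 1]
    cnt <- 0; for (c in codes) if (c == k) cnt <- cnt + 1
    expect_equal(occ[[col]], 100 * cnt / length(codes))
  }
  expect_equal(occ$pct_tspo_total, occ$pct_tspo_only + occ$pct_both)

  # degenerate cases
  dims <- c(10, 1, 1); mask <- array(TRUE, dims)
  none <- synth_binmap(array(FALSE, dims), mask)
  occ0 <- occupancy(combine_categories(none, none, mask))
  expect_equal(c(occ0$pct_neither, occ0$pct_tspo_only, occ0$pct_amyloid_only,
                 occ0$pct_both), c(100, 0, 0, 0))
  half <- synth_binmap(array(rep(c(TRUE, FALSE), 5), dims), mask)
  expect_equal(occupancy(combine_categories(half, none, mask))$pct_tspo_only,
               50)
})

test_that("binary Dice handles identity, disjoint, overlap and empty cases", {
  dims <- c(8, 1, 1); mask <- array(TRUE, dims)
  a <- synth_binmap(array(c(rep(TRUE, 4), rep(FALSE, 4)), dims), mask)
  expect_equal(dice_binary(a, a), 1)
  b <- synth_binmap(array(c(rep(FALSE, 4), rep(TRUE, 4)), dims), mask)
  expect_equal(dice_binary(a, b), 0)
  # |A| = 4, |B| = 4, |A n B| = 2
  c2 <- synth_binmap(array(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                             FALSE), dims), mask)
  expect_equal(dice_binary(a, c2), 0.5)
  e <- synth_binmap(array(FALSE, dims), mask)
  expect_message(d0 <- dice_binary(e, e), "empty")
  expect_equal(d0, 0)
})

test_that("fuzzy Dice reduces to binary Dice on 0/1 fields and is symmetric and bounded", {
  set.seed(22)
  for (rep in 1:10) {
    n <- 300
    av <- as.numeric(runif(n) < 0.4)
    bv <- as.numeric(runif(n) < 0.3)
    ta <- synth_tmap(av); tb <- synth_tmap(bv)
    ba <- synth_binmap(array(av > 0.5, c(n, 1, 1)))
    bb <- synth_binmap(array(bv > 0.5, c(n, 1, 1)))
    expect_equal(dice_continuous(ta, tb), dice_binary(ba, bb),
                 tolerance = 1e-12)
  }
  # graded fields: symmetry and [0, 1] bounds; negative parts ignored
  x <- synth_tmap(rnorm(400)); y <- synth_tmap(rnorm(400, 0.5))
  dxy <- dice_continuous(x, y)
  expect_equal(dxy, dice_continuous(y, x))
  expect_gte(dxy, 0); expect_lte(dxy, 1)
  expect_equal(dice_continuous(x, x), 1)
  neg <- synth_tmap(-abs(rnorm(400)))
  expect_message(dn <- dice_continuous(neg, neg), "vanish")
  expect_equal(dn, 0)
})

test_that("binary Dice is recomputable from the category map alone", {
  for (s in 23:27) {
    cs <- random_category_case(seed = s)
    cm <- combine_categories(cs$ts, cs$am, cs$mask)
    occ <- occupancy(cm)
    from_cat <- if (occ$pct_tspo_total + occ$pct_amyloid_total == 0) 0 else
      2 * occ$pct_both / (occ$pct_tspo_total + occ$pct_amyloid_total)
    expect_equal(dice_binary(cs$ts, cs$am), from_cat, tolerance = 1e-9)
  }
})

test_that("transition flows satisfy the occupancy bookkeeping identity", {
  cs <- random_category_case(seed = 31)
  cm1 <- combine_categories(cs$ts, cs$am, cs$mask, age_months = 5)
  set.seed(32)
  n <- sum(cs$mask)
  ts2 <- synth_binmap(array(runif(n) < 0.6, dim = dim(cs$mask)), cs$mask,
                      age_months = 8)
  am2 <- synth_binmap(array(runif(n) < 0.5, dim = dim(cs$mask)), cs$mask,
                      age_months = 8)
  cm2 <- combine_categories(ts2, am2, cs$mask, age_months = 8)
  tf <- transition_flows(cm1, cm2)
  o1 <- occupancy(cm1); o2 <- occupancy(cm2)
  for (tr in c("tspo", "amyloid")) {
    row <- tf[tf$tracer == tr, ]
    tot1 <- o1[[paste0("pct_", tr, "_total")]]
    tot2 <- o2[[paste0("pct_", tr, "_total")]]
    expect_equal(tot2, tot1 + row$pct_new - row$pct_disappeared,
                 tolerance = 1e-9)
    expect_equal(row$pct_persisting + row$pct_disappeared, tot1,
                 tolerance = 1e-9)
    # voxel-by-voxel bookkeeping oracle
    ef <- cm1$codes[cs$mask] %in% dualpet:::.tracer_codes[[tr]]
    et <- cm2$codes[cs$mask] %in% dualpet:::.tracer_codes[[tr]]
    expect_equal(row$pct_new, 100 * sum(!ef & et) / n)
    expect_equal(row$pct_disappeared, 100 * sum(ef & !et) / n)
  }
  # the 4x4 matrix partitions the brain
  expect_equal(sum(attr(tf, "transition_matrix")), 100, tolerance = 1e-9)

  # identity transition: nothing new, nothing disappears
  cm1b <- combine_categories(cs$ts, cs$am, cs$mask, age_months = 8)
  tf0 <- transition_flows(cm1, cm1b)
  expect_true(all(tf0$pct_new == 0) && all(tf0$pct_disappeared == 0))

  # empty to full
  dims <- dim(cs$mask)
  e <- synth_binmap(array(FALSE, dims), cs$mask, age_months = 5)
  f <- synth_binmap(array(TRUE, dims), cs$mask, age_months = 8)
  tff <- transition_flows(combine_categories(e, e, cs$mask, 5),
                          combine_categories(f, f, cs$mask, 8))
  expect_true(all(tff$pct_new == 100) && all(tff$pct_disappeared == 0))

  expect_error(transition_flows(cm2, cm1), "age_from")
})
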