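test_that("identical rng state gives bit-identical images; distinct states differ", {
  atlas <- test_atlas()
  p <- pathology_params()
  i1 <- simulate_subject(atlas, "TG", 13, p, "tspo", 42L)
  i2 <- simulate_subject(atlas, "TG", 13, p, "tspo", 42L)
  i3 <- simulate_subject(atlas, "TG", 13, p, "tspo", 43L)
  expect_identical(i1$data, i2$data)
  expect_false(identical(i1$data, i3$data))
})

test_that("noise-free wild-type and pre-onset transgenic images have SUVR exactly 1", {
  atlas <- test_atlas()
  p <- params_noiseless()
  ref <- voi_mask(atlas, "ref_wm_amyloid")
  wt <- simulate_subject(atlas, "WT", 14, p, "amyloid", 7L)
  for (voi in c("target_forebrain", "frontal_cortex", "hippocampus",
                "cerebellum")) {
    expect_equal(compute_suvr(wt, voi_mask(atlas, voi), ref), 1.0)
  }
  # transgenic below every amyloid onset age: no deposition anywhere
  tg <- simulate_subject(atlas, "TG", 5, p, "amyloid", 8L)
  expect_equal(compute_suvr(tg, voi_mask(atlas, "target_forebrain"), ref), 1.0)
})

test_that("transgenic amyloid burden is nondecreasing in age and matches the logistic closed form", {
  p <- pathology_params()
  ages <- c(5, 8, 13, 16)
  for (region in c("frontal_cortex", "parietal_cortex", "hippocampus",
                   "thalamus", "other_brain")) {
    b <- region_burden(p, region, ages, "amyloid")
    expect_true(all(diff(b) >= 0))
    # independent evaluation of the hinged logistic
    onset <- p$amyloid_onset[[region]]
    amp <- p$amyloid_region_amp[[region]]
    expected <- amp * pmax(0, 2 / (1 + exp(-p$amyloid_growth *
                                             (ages - onset))) - 1)
    expect_equal(b, expected, tolerance = 1e-12)
  }
  expect_equal(region_burden(p, "frontal_cortex", c(5, 8, 13), "amyloid",
                             genotype = "WT"), c(0, 0, 0))
})

test_that("inflammation is established before amyloid in every cortical region", {
  p <- pathology_params()
  ages <- seq(0, 24, by = 0.1)
  thresh <- 0.1
  for (region in c("frontal_cortex", "parietal_cortex",
                   "piriform_entorhinal_cortex")) {
    first_cross <- function(tracer)
      ages[which(region_burden(p, region, ages, tracer) > thresh)[1]]
    expect_lt(first_cross("tspo"), first_cross("amyloid"))
  }
})

test_that("cohort bookkeeping: counts, determinism, and per-subject substreams", {
  atlas <- test_atlas()
  des <- cohort_design(ages = c(5, 16), n_per_group = 2, seed = 11L)
  co <- simulate_cohort(des, pathology_params(), atlas)
  # 2 genotypes x 2 ages x 2 animals x 2 tracers
  expect_length(co$images, 16)
  expect_equal(nrow(co$manifest), 16)
  expect_equal(nrow(co$biomarkers), 8)

  co2 <- simulate_cohort(des, pathology_params(), atlas)
  expect_identical(co$biomarkers, co2$biomarkers)
  expect_identical(co$images[["tg_05mo_01.tspo"]]$data,
                   co2$images[["tg_05mo_01.tspo"]]$data)

  # a cohort image equals the same subject simulated standalone from its
  # own recorded substream seed (order independence)
  row <- co$manifest[co$manifest$subject_id == "wt_16mo_02" &
                       co$manifest$tracer == "amyloid", ]
  solo <- simulate_subject(atlas, "WT", 16, pathology_params(), "amyloid",
                           row$seed)
  expect_identical(solo$data, co$images[["wt_16mo_02.amyloid"]]$data)
})

test_that("with zero biomarker noise, sTREM2 rank order follows forebrain inflammation burden", {
  atlas <- test_atlas()
  cvs <- pathology_params()$biomarker_cv
  p <- pathology_params(biomarker_cv = setNames(rep(0, length(cvs)),
                                                names(cvs)))
  des <- cohort_design(ages = c(13), n_per_group = 8, genotypes = "TG",
                       tracers = "tspo", seed = 3L)
  co <- simulate_cohort(des, p, atlas)
  # burden ranks are the ranks of the per-animal multiplier, recovered from
  # each subject's recorded seed
  L <- vapply(unique(co$manifest$seed), function(s)
    dualpet:::subject_multiplier(s, p), numeric(1))
  expect_equal(order(co$biomarkers$sTREM2), order(L))
  # total Abeta is driven by the same multiplier (monotone too)
  expect_equal(order(co$biomarkers$total_Abeta), order(L))
})

test_that("null generator makes genotypes exchangeable (KS rejects at about the nominal rate)", {
  atlas <- test_atlas()
  p <- params_null(noise_fwhm_mm = 0)
  rej <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_design(ages = 8, n_per_group = 8,
                                        tracers = "tspo", seed = s),
                          p, atlas)
    st <- cohort_suvr_table(co)
    suppressWarnings(
      stats::ks.test(st$suvr[st$genotype == "TG"],
                     st$suvr[st$genotype == "WT"])$p.value) < 0.05
  }, logical(1))
  # nominal 5% rate; binomial noise at 40 replicates allows up to ~6
  expect_lte(sum(rej), 6)
})

test_that("expected transgenic forebrain SUVR is nondecreasing in age for both tracers", {
  atlas <- test_atlas()
  p <- params_noiseless(subject_cv = 0)
  for (tr in c("tspo", "amyloid")) {
    suvrs <- vapply(c(5, 8, 13, 16), function(a) {
      img <- simulate_subject(atlas, "TG", a, p, tr, 1L)
      compute_suvr(img, voi_mask(atlas, "target_forebrain"),
                   voi_mask(atlas, dualpet:::ref_voi_for_tracer(tr)))
    }, numeric(1))
    expect_true(all(diff(suvrs) >= -1e-12))
  }
})

test_that("unknown tracer or genotype is rejected", {
  atlas <- test_atlas()
  p <- pathology_params()
  expect_error(simulate_subject(atlas, "TG", 5, p, "fdg", 1L),
               "unknown tracer")
  expect_error(simulate_subject(atlas, "het", 5, p, "tspo", 1L),
               "unknown genotype")
  expect_error(cohort_design(n_per_group = 1), "n_per_group")
  expect_error(cohort_design(ages = c(8, 5)), "increasing")
})
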