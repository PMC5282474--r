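# Hinged logistic growth: exactly 0 up to onset, then rises to 1.
hinge_logistic <- function(age, onset, growth) {
  pmax(0, 2 * plogis(growth * (age - onset)) - 1)
}

#' Expected regional burden of the phantom pathology model
#'
#' Temporal burden kernel for one region, noise-free and at unit per-animal
#' multiplier: the quantity the spatial fields are built from. For the
#' amyloid tracer this is the region amplitude times the hinged logistic in
#' age (zero for wild-type). For the TSPO tracer it is the diffuse
#' inflammation ramp plus the plaque-associated component plus the wild-type
#' aging drift.
#'
#' @param params a [pathology_params()].
#' @param region region name (see [atlas_region_table()], plus
#'   `"other_brain"`).
#' @param age age in months.
#' @param tracer `"tspo"` or `"amyloid"`.
#' @param genotype `"TG"` or `"WT"`.
#' @return numeric burden (vectorized over `age`).
#' @export
region_burden <- function(params, region, age, tracer, genotype = "TG") {
  check_tracer(tracer)
  check_genotype(genotype)
  assert_that(all(age >= 0), "age must be nonnegative")
  assert_that(region %in% names(params$amyloid_onset),
              "unknown region '%s'", region)
  amp <- params$amyloid_region_amp[[region]]
  amy <- amp * hinge_logistic(age, params$amyloid_onset[[region]],
                              params$amyloid_growth)
  if (tracer == "amyloid") {
    return(if (genotype == "TG") amy else 0 * age)
  }
  drift <- params$wt_drift_per_month * age
  if (genotype == "WT") return(drift)
  ramp <- hinge_logistic(age, params$inflam_onset, params$inflam_growth)
  w <- params$diffuse_region_weight[[region]]
  w * ramp + params$plaque_weight * amy + drift
}

# Per-voxel amyloid burden field for a TG animal at unit multiplier:
# per-region amplitude * hinged logistic, smoothed into focal deposits,
# masked to the brain with reference regions zeroed.
amyloid_field <- function(atlas, params, age) {
  region_vals <- params$amyloid_region_amp *
    hinge_logistic(age, params$amyloid_onset, params$amyloid_growth)
  lut <- c(0, region_vals[atlas$region_names])  # index 1 = label 0
  f <- array(lut[atlas$labels + 1L], dim = dim(atlas$labels))
  if (params$amyloid_fwhm_mm > 0 && any(f > 0)) {
    f <- smooth_array(f, params$amyloid_fwhm_mm, atlas$grid$voxel_size)
  }
  mask_field(f, atlas)
}

# Diffuse inflammation topography: smoothed region-weighted indicator
# (cortex-dominant), normalized to peak 1. Age-independent.
diffuse_map <- function(atlas, params) {
  w <- params$diffuse_region_weight
  lut <- c(0, w[atlas$region_names])
  lut[is.na(lut)] <- 0
  ind <- array(lut[atlas$labels + 1L], dim = dim(atlas$labels))
  if (params$diffuse_fwhm_mm > 0) {
    ind <- smooth_array(ind, params$diffuse_fwhm_mm, atlas$grid$voxel_size)
  }
  if (max(ind) > 0) ind <- ind / max(ind)
  mask_field(ind, atlas)
}

# Inflammation burden field at unit multiplier for one genotype.
inflam_field <- function(atlas, params, age, genotype) {
  drift <- params$wt_drift_per_month * age * nonref_mask(atlas)
  if (genotype == "WT") return(mask_field(drift, atlas))
  ramp <- hinge_logistic(age, params$inflam_onset, params$inflam_growth)
  f <- ramp * diffuse_map(atlas, params) +
    params$plaque_weight * amyloid_field(atlas, params, age) + drift
  mask_field(f, atlas)
}

# zero a field outside the brain and inside both reference regions:
# reference tissue is pathology-free by assumption (SUVR requires it)
mask_field <- function(f, atlas) {
  f[!brain_mask(atlas)] <- 0
  f[voi_mask(atlas, "ref_wm_tspo")] <- 0
  f[voi_mask(atlas, "ref_wm_amyloid")] <- 0
  f
}

nonref_mask <- function(atlas) {
  m <- brain_mask(atlas) & !voi_mask(atlas, "ref_wm_tspo") &
    !voi_mask(atlas, "ref_wm_amyloid")
  array(as.numeric(m), dim = dim(atlas$labels))
}

# tracer-specific global amplitude and subject-multiplier exponent
tracer_k <- function(params, tracer) {
  switch(tracer, tspo = params$k_inflam, amyloid = params$k_amyloid)
}
tracer_gamma <- function(params, tracer) {
  switch(tracer, tspo = params$subject_exp_inflam,
         amyloid = params$subject_exp_amyloid)
}

burden_field <- function(atlas, params, age, genotype, tracer) {
  if (tracer == "amyloid") {
    if (genotype == "WT") return(array(0, dim = dim(atlas$labels)))
    amyloid_field(atlas, params, age)
  } else {
    inflam_field(atlas, params, age, genotype)
  }
}

# per-animal lognormal burden multiplier, shared between tracers
subject_multiplier <- function(subject_seed, params) {
  z <- with_seed(mix_seed(subject_seed, 101L), rnorm(1))
  exp(params$subject_cv * z)
}

# assemble one image from a precomputed burden field
assemble_image <- function(atlas, params, field, tracer, L, noise_seed) {
  k <- tracer_k(params, tracer)
  gam <- tracer_gamma(params, tracer)
  bm <- brain_mask(atlas)
  img <- array(0, dim = dim(atlas$labels))
  img[bm] <- 1 + k * field[bm] * L^gam
  if (params$noise_sd > 0) {
    if (params$noise_fwhm_mm > 0) {
      noise <- with_seed(noise_seed,
                         array(rnorm(length(img)), dim = dim(img)))
      noise <- smooth_array(noise, params$noise_fwhm_mm,
                            atlas$grid$voxel_size)
      noise <- noise * (params$noise_sd / stats::sd(as.vector(noise)))
      img[bm] <- img[bm] + noise[bm]
    } else {
      img[bm] <- img[bm] + with_seed(noise_seed,
                                     rnorm(sum(bm), sd = params$noise_sd))
    }
  }
  image_volume(img, atlas$grid)
}

#' Simulate one subject's tracer image
#'
#' Generates a single reference-scaled uptake image: expectation 1 in the
#' reference regions, `1 + k * burden` elsewhere in the brain, plus additive
#' Gaussian voxel noise. Identical `rng_state` gives a bit-identical image;
#' the per-animal burden multiplier is derived from `rng_state` alone, so the
#' two tracer images of one animal share it.
#'
#' @param atlas a `region_atlas` from [build_atlas()].
#' @param genotype `"TG"` or `"WT"`.
#' @param age age in months, `>= 0`.
#' @param params a [pathology_params()].
#' @param tracer `"tspo"` or `"amyloid"`.
#' @param rng_state integer subject seed.
#' @return an [image_volume()].
#' @examples
#' atlas <- build_atlas()
#' p <- pathology_params(noise_sd = 0)
#' img <- simulate_subject(atlas, "WT", 5, p, "amyloid", 1L)
#' compute_suvr(img, voi_mask(atlas, "target_forebrain"),
#'              voi_mask(atlas, "ref_wm_amyloid"))  # exactly 1
#' @export
simulate_subject <- function(atlas, genotype, age, params, tracer, rng_state) {
  assert_that(inherits(atlas, "region_atlas"), "atlas must be a region_atlas")
  assert_that(inherits(params, "pathology_params"),
              "params must be a pathology_params")
  check_genotype(genotype)
  check_tracer(tracer)
  assert_that(is.numeric(age) && length(age) == 1 && age >= 0,
              "age must be a single nonnegative number")
  L <- subject_multiplier(rng_state, params)
  field <- burden_field(atlas, params, age, genotype, tracer)
  assemble_image(atlas, params, field, tracer, L,
                 mix_seed(rng_state, 102L, .tracers[[tracer]]))
}

subject_seed <- function(master, genotype, age, rep) {
  mix_seed(master, .genotypes[[genotype]], round(age * 10), rep)
}

# terminal biomarker draw for one animal given its forebrain burdens
draw_biomarkers <- function(params, b_inflam, b_amyloid, seed) {
  src <- c(sTREM2 = b_inflam, total_Abeta = b_amyloid, IL1b = b_inflam,
           IL6 = b_inflam, KCGRO = b_inflam)
  cv <- params$biomarker_cv
  z <- with_seed(seed, rnorm(length(src)))
  # mean-one multiplicative lognormal noise
  vals <- params$biomarker_base * (1 + params$biomarker_coupling * src) *
    exp(cv * z - cv^2 / 2)
  as.list(vals)
}

#' Simulate a full cross-sectional dual-tracer cohort
#'
#' Generates one image per subject per tracer plus a terminal biomarker table.
#' Each animal owns an independent random substream derived from the master
#' seed and its identity (genotype, age, replicate), so regeneration under the
#' same seed is bit-identical and does not depend on enumeration order.
#' Biomarkers are monotone functions of the animal's own forebrain burden
#' (sTREM2 and cytokines from inflammation, total Abeta from amyloid) with
#' multiplicative mean-one lognormal noise.
#'
#' @param design a [cohort_design()].
#' @param params a [pathology_params()].
#' @param atlas optional prebuilt `region_atlas`; built on [default_grid()]
#'   when omitted.
#' @return an object of class `phantom_cohort`: a list with `atlas`,
#'   `images` (named list of [image_volume()], keys `"<subject_id>.<tracer>"`),
#'   `manifest` (data frame: subject_id, genotype, age_months, tracer, path,
#'   seed) and `biomarkers` (data frame: subject_id, genotype, age_months,
#'   sTREM2, total_Abeta, IL1b, IL6, KCGRO).
#' @export
simulate_cohort <- function(design, params = pathology_params(),
                            atlas = NULL) {
  assert_that(inherits(design, "cohort_design"),
              "design must be a cohort_design")
  assert_that(inherits(params, "pathology_params"),
              "params must be a pathology_params")
  if (is.null(atlas)) atlas <- build_atlas()
  fb <- voi_mask(atlas, "target_forebrain")

  images <- list()
  manifest <- list()
  biomarkers <- list()
  for (genotype in design$genotypes) {
    for (age in design$ages) {
      fields <- lapply(setNames(design$tracers, design$tracers), function(tr)
        burden_field(atlas, params, age, genotype, tr))
      # forebrain burden means for the biomarker model (both pathologies,
      # regardless of which tracers are imaged)
      fb_inflam <- mean(inflam_field(atlas, params, age, genotype)[fb])
      fb_amy <- if (genotype == "TG")
        mean(amyloid_field(atlas, params, age)[fb]) else 0
      for (rep in seq_len(design$n_per_group)) {
        sid <- sprintf("%s_%02.0fmo_%02d", tolower(genotype), age, rep)
        sseed <- subject_seed(design$seed, genotype, age, rep)
        L <- subject_multiplier(sseed, params)
        for (tr in design$tracers) {
          img <- assemble_image(atlas, params, fields[[tr]], tr, L,
                                mix_seed(sseed, 102L, .tracers[[tr]]))
          images[[paste(sid, tr, sep = ".")]] <- img
          manifest[[length(manifest) + 1L]] <-
            data.frame(subject_id = sid, genotype = genotype,
                       age_months = age, tracer = tr, path = NA_character_,
                       seed = sseed, stringsAsFactors = FALSE)
        }
        bm <- draw_biomarkers(params,
                              fb_inflam * L^params$subject_exp_inflam,
                              fb_amy * L^params$subject_exp_amyloid,
                              mix_seed(sseed, 103L))
        biomarkers[[length(biomarkers) + 1L]] <-
          cbind(data.frame(subject_id = sid, genotype = genotype,
                           age_months = age, stringsAsFactors = FALSE),
                as.data.frame(bm))
      }
    }
  }
  structure(list(design = design, params = params, atlas = atlas,
                 images = images,
                 manifest = do.call(rbind, manifest),
                 biomarkers = do.call(rbind, biomarkers)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d images (%d subjects x %d tracer(s)), %d biomarker rows\n",
              length(x$images), nrow(x$biomarkers),
              length(x$design$tracers), nrow(x$biomarkers)))
  invisible(x)
}
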