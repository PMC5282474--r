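#' Cohort design for the cross-sectional phantom study
#'
#' Mirrors the cross-sectional design of dual-tracer transgenic-versus-wild-type
#' mouse studies: equal-sized genotype groups at each of several ages, each
#' animal imaged with both tracers. Equal group sizes are required by the
#' voxel-wise statistics stage.
#'
#' @param ages age groups in months, strictly increasing (default
#'   `c(5, 8, 13, 16)`).
#' @param n_per_group animals per genotype per age (default 8; must be >= 2).
#' @param genotypes character, subset of `c("TG", "WT")`.
#' @param tracers character, subset of `c("tspo", "amyloid")`.
#' @param seed master seed for the cohort (integer).
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(ages = c(5, 8, 13, 16), n_per_group = 8L,
                          genotypes = c("TG", "WT"),
                          tracers = c("tspo", "amyloid"), seed = 1L) {
  assert_that(is.numeric(ages) && length(ages) >= 1 && all(is.finite(ages)) &&
                all(ages >= 0) && !is.unsorted(ages, strictly = TRUE),
              "ages must be strictly increasing and nonnegative")
  assert_that(is.numeric(n_per_group) && length(n_per_group) == 1 &&
                n_per_group == round(n_per_group) && n_per_group >= 2,
              "n_per_group must be an integer >= 2 (voxel-wise t-test undefined below 2)")
  assert_that(all(genotypes %in% names(.genotypes)) && length(genotypes) >= 1,
              "genotypes must be a subset of TG, WT")
  assert_that(all(tracers %in% names(.tracers)) && length(tracers) >= 1,
              "tracers must be a subset of tspo, amyloid")
  structure(list(ages = as.numeric(ages), n_per_group = as.integer(n_per_group),
                 genotypes = genotypes, tracers = tracers,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Pathology model parameters for the phantom generator
#'
#' Defaults encode the study conditions the package emulates: widespread
#' microglial activation (TSPO signal) already present at the youngest age,
#' regionally focal amyloid deposition starting later, spatial convergence of
#' the two signals at the oldest ages, a mild linear TSPO drift in aging
#' wild-type animals, and terminal fluid biomarkers coupled to each animal's
#' own forebrain burden.
#'
#' Amyloid burden in transgenic animals follows a per-region hinged logistic
#' in age: zero up to the region onset, then `2 * plogis(growth * (age -
#' onset)) - 1`, saturating at 1. Inflammation burden is a diffuse
#' spatially-smooth field gated by its own early-onset ramp plus a
#' plaque-associated component proportional to local amyloid burden, plus the
#' wild-type drift. Per-animal heterogeneity enters as a shared lognormal
#' burden multiplier with tracer-specific exponents.
#'
#' @param ... named overrides of the defaults listed below.
#' @return an object of class `pathology_params` (a named list).
#'
#' @section Parameters:
#' \describe{
#'   \item{amyloid_onset}{per-region onset age (months) of amyloid growth.}
#'   \item{amyloid_growth}{logistic growth rate (1/month), shared.}
#'   \item{amyloid_region_amp}{per-region relative amyloid amplitude.}
#'   \item{k_amyloid, k_inflam}{global signal amplitudes: fractional SUVR
#'     excess at unit burden.}
#'   \item{inflam_onset, inflam_growth}{onset (months) and rate of the
#'     diffuse inflammation ramp.}
#'   \item{diffuse_region_weight}{per-region weight of the diffuse
#'     inflammation topography (cortex-dominant, graded elsewhere).}
#'   \item{diffuse_fwhm_mm}{spatial extent (mm) of the smoothed diffuse
#'     inflammation field.}
#'   \item{plaque_weight}{weight of the plaque-associated (amyloid-locked)
#'     inflammation component.}
#'   \item{wt_drift_per_month}{linear wild-type TSPO burden drift (1/month),
#'     applied to both genotypes outside the reference regions.}
#'   \item{amyloid_fwhm_mm}{smoothing (mm) applied to the blocky per-region
#'     amyloid field to create focal deposits.}
#'   \item{noise_sd}{additive Gaussian voxel noise SD (image units).}
#'   \item{noise_fwhm_mm}{spatial correlation length of the voxel noise
#'     (mm FWHM; 0 = independent).}
#'   \item{subject_cv}{SD of the log per-animal burden multiplier.}
#'   \item{subject_exp_amyloid, subject_exp_inflam}{tracer-specific exponents
#'     applied to the shared multiplier (amyloid load is more heterogeneous
#'     across animals than glial activation).}
#'   \item{biomarker_base}{baseline concentrations (pg/ml-like) of sTREM2,
#'     total Abeta and cytokines IL-1b, IL-6, KC/GRO.}
#'   \item{biomarker_coupling}{linear coupling of each biomarker to the
#'     animal's forebrain inflammation (sTREM2, cytokines) or amyloid
#'     (total Abeta) burden.}
#'   \item{biomarker_cv}{lognormal noise CV per biomarker.}
#' }
#' @export
pathology_params <- function(...) {
  defaults <- list(
    amyloid_onset = c(frontal_cortex = 6.0, parietal_cortex = 6.8,
                      thalamus = 8.0, hippocampus = 9.5,
                      piriform_entorhinal_cortex = 10.0, other_brain = 12.0,
                      cerebellum = 14.0, brainstem = Inf,
                      ref_wm_tspo = Inf, ref_wm_amyloid = Inf),
    amyloid_growth = 0.35,
    amyloid_region_amp = c(frontal_cortex = 1.0, parietal_cortex = 0.95,
                           thalamus = 0.85, hippocampus = 0.8,
                           piriform_entorhinal_cortex = 0.7,
                           other_brain = 0.3, cerebellum = 0.15,
                           brainstem = 0, ref_wm_tspo = 0, ref_wm_amyloid = 0),
    k_amyloid = 0.75,
    k_inflam = 0.35,
    inflam_onset = 3.5,
    inflam_growth = 0.25,
    diffuse_region_weight = c(frontal_cortex = 1.0, parietal_cortex = 1.0,
                              piriform_entorhinal_cortex = 0.85,
                              hippocampus = 0.6, thalamus = 0.6,
                              other_brain = 0.45, cerebellum = 0.7,
                              brainstem = 0, ref_wm_tspo = 0,
                              ref_wm_amyloid = 0),
    diffuse_fwhm_mm = 2.0,
    plaque_weight = 0.8,
    wt_drift_per_month = 0.004,
    amyloid_fwhm_mm = 0.8,
    noise_sd = 0.05,
    noise_fwhm_mm = 1.2,
    subject_cv = 0.20,
    subject_exp_amyloid = 2.0,
    subject_exp_inflam = 0.8,
    biomarker_base = c(sTREM2 = 1500, total_Abeta = 400, IL1b = 20,
                       IL6 = 15, KCGRO = 30),
    biomarker_coupling = c(sTREM2 = 5.0, total_Abeta = 3.0, IL1b = 0.8,
                           IL6 = 0.6, KCGRO = 0.7),
    biomarker_cv = c(sTREM2 = 0.07, total_Abeta = 0.15, IL1b = 0.25,
                     IL6 = 0.25, KCGRO = 0.25)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  assert_that(length(bad) == 0, "unknown pathology parameter(s): %s",
              paste(bad, collapse = ", "))
  p <- defaults
  for (nm in names(over)) {
    v <- over[[nm]]
    if (is.list(v)) v <- unlist(v)  # tolerate YAML/JSON-parsed overrides
    if (!is.null(names(defaults[[nm]])) && !is.null(names(v))) {
      d <- defaults[[nm]]
      d[names(v)] <- v
      v <- d
    }
    p[[nm]] <- v
  }
  for (nm in c("amyloid_growth", "k_amyloid", "k_inflam", "inflam_growth",
               "diffuse_fwhm_mm", "plaque_weight", "wt_drift_per_month",
               "amyloid_fwhm_mm", "noise_sd", "noise_fwhm_mm", "subject_cv",
               "subject_exp_amyloid", "subject_exp_inflam")) {
    assert_that(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 && p[[nm]] >= 0,
                "parameter '%s' must be a single nonnegative number", nm)
  }
  assert_that(all(p$amyloid_region_amp >= 0) &&
                all(p$biomarker_coupling >= 0) && all(p$biomarker_cv >= 0) &&
                all(p$biomarker_base > 0),
              "amplitudes, couplings, CVs must be nonnegative; bases positive")
  structure(p, class = "pathology_params")
}
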