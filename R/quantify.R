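#' VOI mean uptake
#'
#' Arithmetic mean of image values inside a voxel mask.
#'
#' @param image an [image_volume()].
#' @param mask logical array on the image grid.
#' @return numeric scalar.
#' @export
voi_mean <- function(image, mask) {
  assert_that(inherits(image, "image_volume"), "image must be an image_volume")
  assert_that(is.logical(mask) && identical(dim(mask), dim(image$data)),
              "mask must be a logical array on the image grid")
  assert_that(any(mask), "mask is empty")
  mean(image$data[mask])
}

#' Reference-region SUVR
#'
#' Standardized uptake value ratio: mean uptake in the target VOI divided by
#' mean uptake in the (assumed pathology-free) reference VOI. The caller
#' selects the tracer-appropriate reference: the TSPO tracer is scaled by the
#' cerebellar/brainstem white-matter reference, the amyloid tracer by the
#' pons/midbrain/hindbrain white-matter reference.
#'
#' @param image an [image_volume()], already co-registered to the mask grid.
#' @param target logical target mask.
#' @param reference logical reference mask; its mean uptake must be positive.
#' @return SUVR (dimensionless).
#' @export
compute_suvr <- function(image, target, reference) {
  ref <- voi_mean(image, reference)
  assert_that(ref > 0,
              "reference VOI mean is not positive (%.4g): corrupt image?", ref)
  voi_mean(image, target) / ref
}

#' Percent change between two group means
#'
#' `100 * (later - baseline) / baseline`, the contrast convention used for
#' reporting longitudinal biomarker increases (e.g. a tripling plus a bit,
#' 1.0 to 3.11, is +211 percent).
#'
#' @param mean_later,mean_baseline group means; `mean_baseline` must be
#'   positive.
#' @return percent change (numeric).
#' @export
percent_change <- function(mean_later, mean_baseline) {
  assert_that(is.numeric(mean_later) && is.numeric(mean_baseline),
              "means must be numeric")
  assert_that(all(mean_baseline > 0), "baseline mean must be positive")
  100 * (mean_later - mean_baseline) / mean_baseline
}

#' SUVR table for a simulated cohort
#'
#' Computes the forebrain SUVR endpoint for every subject and tracer in a
#' [simulate_cohort()] result, scaling each tracer by its own white-matter
#' reference region.
#'
#' @param cohort a `phantom_cohort`.
#' @param target_voi target VOI name (default `"target_forebrain"`).
#' @return data frame: subject_id, genotype, age_months, tracer, target_voi,
#'   suvr.
#' @export
cohort_suvr_table <- function(cohort, target_voi = "target_forebrain") {
  assert_that(inherits(cohort, "phantom_cohort"),
              "cohort must be a phantom_cohort")
  atlas <- cohort$atlas
  tgt <- voi_mask(atlas, target_voi)
  refs <- lapply(setNames(cohort$design$tracers, cohort$design$tracers),
                 function(tr) voi_mask(atlas, ref_voi_for_tracer(tr)))
  m <- cohort$manifest
  suvr <- vapply(seq_len(nrow(m)), function(i) {
    img <- cohort$images[[paste(m$subject_id[i], m$tracer[i], sep = ".")]]
    compute_suvr(img, tgt, refs[[m$tracer[i]]])
  }, numeric(1))
  data.frame(subject_id = m$subject_id, genotype = m$genotype,
             age_months = m$age_months, tracer = m$tracer,
             target_voi = target_voi, suvr = suvr, stringsAsFactors = FALSE)
}

#' Group summaries of a long measurement table
#'
#' Mean and unbiased (n-1) SD per genotype, age and measure, ordered by
#' genotype then age. Cells with fewer than two observations are an error
#' (the downstream standardized-difference and t statistics need an SD).
#'
#' @param records data frame with columns `genotype`, `age_months`, `measure`
#'   and `value`.
#' @return data frame: genotype, age_months, measure, n, mean, sd.
#' @export
summarize_groups <- function(records) {
  need <- c("genotype", "age_months", "measure", "value")
  assert_that(is.data.frame(records) && all(need %in% names(records)),
              "records must have columns: %s", paste(need, collapse = ", "))
  key <- interaction(records$genotype, records$age_months, records$measure,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    assert_that(nrow(d) >= 2,
                "singleton cell: genotype=%s age=%s measure=%s (n=%d)",
                d$genotype[1], format(d$age_months[1]), d$measure[1], nrow(d))
    data.frame(genotype = d$genotype[1], age_months = d$age_months[1],
               measure = d$measure[1], n = nrow(d), mean = mean(d$value),
               sd = sd(d$value), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$measure, out$genotype, out$age_months), ]
  rownames(out) <- NULL
  out
}
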