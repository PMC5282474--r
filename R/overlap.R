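#' Combine the two tracers' significance maps into a four-category map
#'
#' Fixed per-voxel legend: 0 = elevated for neither tracer, 1 = elevated for
#' the TSPO tracer only, 2 = elevated for the amyloid tracer only, 3 =
#' elevated for both.
#'
#' @param tspo,amyloid `binary_map`s for the same age group, on one grid.
#' @param brain_mask logical brain mask on the same grid.
#' @param age_months optional metadata.
#' @return an object of class `category_map`: integer array `codes` (NA
#'   outside the mask), `mask`, `age_months`.
#' @export
combine_categories <- function(tspo, amyloid, brain_mask,
                               age_months = NA_real_) {
  assert_that(inherits(tspo, "binary_map") && inherits(amyloid, "binary_map"),
              "inputs must be binary_map objects")
  assert_that(identical(dim(tspo$elevated), dim(amyloid$elevated)) &&
                identical(dim(tspo$elevated), dim(brain_mask)),
              "grid mismatch between maps and brain mask")
  codes <- array(NA_integer_, dim = dim(brain_mask))
  codes[brain_mask] <- as.integer(tspo$elevated[brain_mask]) +
    2L * as.integer(amyloid$elevated[brain_mask])
  structure(list(codes = codes, mask = brain_mask, age_months = age_months),
            class = "category_map")
}

#' Percent occupancy of the four overlap categories
#'
#' Each category's voxel count as a percentage of the whole brain-mask
#' volume, plus per-tracer totals (tracer-only + both).
#'
#' @param cat a `category_map`.
#' @param brain_mask logical mask; defaults to the map's own mask.
#' @return one-row data frame: age_months, pct_neither, pct_tspo_only,
#'   pct_amyloid_only, pct_both, pct_tspo_total, pct_amyloid_total.
#' @export
occupancy <- function(cat, brain_mask = cat$mask) {
  assert_that(inherits(cat, "category_map"), "cat must be a category_map")
  assert_that(any(brain_mask), "brain mask is empty")
  codes <- cat$codes[brain_mask]
  n <- length(codes)
  pct <- vapply(0:3, function(k) 100 * sum(codes == k) / n, numeric(1))
  data.frame(age_months = cat$age_months,
             pct_neither = pct[1], pct_tspo_only = pct[2],
             pct_amyloid_only = pct[3], pct_both = pct[4],
             pct_tspo_total = pct[2] + pct[4],
             pct_amyloid_total = pct[3] + pct[4])
}

#' Dice overlap of two binarized significance maps
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 0 (with a message) when both
#' maps are empty.
#'
#' @param a,b `binary_map`s on one grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_binary <- function(a, b) {
  assert_that(inherits(a, "binary_map") && inherits(b, "binary_map"),
              "inputs must be binary_map objects")
  assert_that(identical(dim(a$elevated), dim(b$elevated)), "grid mismatch")
  na <- sum(a$elevated)
  nb <- sum(b$elevated)
  if (na + nb == 0) {
    message("dice_binary: both maps empty; returning 0")
    return(0)
  }
  2 * sum(a$elevated & b$elevated) / (na + nb)
}

#' Fuzzy Dice agreement of two non-binarized t-score maps
#'
#' Magnitude-weighted agreement of the positive parts of two t-fields over
#' the brain mask: `2 * sum(min(a+, b+)) / (sum(a+) + sum(b+))` with
#' `x+ = max(x, 0)`. On \{0, 1\}-valued fields this reduces exactly to
#' [dice_binary()]; on graded fields it additionally weights agreement by
#' regional effect magnitude. Returns 0 (with a message) when both positive
#' parts vanish.
#'
#' @param a,b `t_score_map`s on one grid.
#' @param brain_mask logical mask; defaults to `a$mask`.
#' @return fuzzy Dice coefficient in \[0, 1\].
#' @export
dice_continuous <- function(a, b, brain_mask = a$mask) {
  assert_that(inherits(a, "t_score_map") && inherits(b, "t_score_map"),
              "inputs must be t_score_map objects")
  assert_that(identical(dim(a$t), dim(b$t)) &&
                identical(dim(a$t), dim(brain_mask)), "grid mismatch")
  ap <- pmax(a$t[brain_mask], 0)
  bp <- pmax(b$t[brain_mask], 0)
  denom <- sum(ap) + sum(bp)
  if (denom == 0) {
    message("dice_continuous: both positive parts vanish; returning 0")
    return(0)
  }
  2 * sum(pmin(ap, bp)) / denom
}

# elevation status per tracer encoded in category codes
.tracer_codes <- list(tspo = c(1L, 3L), amyloid = c(2L, 3L))

#' Inter-age transition flows of tracer elevation
#'
#' Classifies every brain-mask voxel, per tracer, as persisting, newly
#' presenting, or disappearing between two age groups' category maps, and
#' reports each class as a percentage of whole-brain volume (so that
#' occupancy(to) = occupancy(from) + new - disappeared). The full 4 x 4
#' category transition matrix (percent of brain volume) is attached as
#' attribute `"transition_matrix"`.
#'
#' @param cat_from,cat_to `category_map`s of the earlier and later age.
#' @param brain_mask logical mask; defaults to `cat_from$mask`.
#' @return data frame with one row per tracer: age_from, age_to, tracer,
#'   pct_persisting, pct_new, pct_disappeared.
#' @export
transition_flows <- function(cat_from, cat_to, brain_mask = cat_from$mask) {
  assert_that(inherits(cat_from, "category_map") &&
                inherits(cat_to, "category_map"),
              "inputs must be category_map objects")
  assert_that(identical(dim(cat_from$codes), dim(cat_to$codes)),
              "grid mismatch")
  assert_that(is.na(cat_from$age_months) || is.na(cat_to$age_months) ||
                cat_from$age_months < cat_to$age_months,
              "age_from (%s) must be below age_to (%s)",
              format(cat_from$age_months), format(cat_to$age_months))
  f <- cat_from$codes[brain_mask]
  t <- cat_to$codes[brain_mask]
  n <- length(f)
  out <- do.call(rbind, lapply(names(.tracer_codes), function(tr) {
    ef <- f %in% .tracer_codes[[tr]]
    et <- t %in% .tracer_codes[[tr]]
    data.frame(age_from = cat_from$age_months, age_to = cat_to$age_months,
               tracer = tr,
               pct_persisting = 100 * sum(ef & et) / n,
               pct_new = 100 * sum(!ef & et) / n,
               pct_disappeared = 100 * sum(ef & !et) / n,
               stringsAsFactors = FALSE)
  }))
  tm <- matrix(0, 4, 4, dimnames = list(from = 0:3, to = 0:3))
  for (i in 0:3) for (j in 0:3) {
    tm[i + 1, j + 1] <- 100 * sum(f == i & t == j) / n
  }
  attr(out, "transition_matrix") <- tm
  out
}
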