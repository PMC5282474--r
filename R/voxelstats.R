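#' Voxel-wise two-sample t-test between groups of images
#'
#' Pooled-variance Student t statistic (transgenic minus wild-type) at every
#' voxel of the brain mask, with `df = n1 + n2 - 2` and, by default, the
#' one-sided p-value for the elevation contrast TG > WT (the contrast that is
#' subsequently binarized). Group sizes must be equal, as required for the
#' balanced statistical parametric mapping design. Voxels with zero pooled
#' variance get `t = 0, p = 1` (counted in a message).
#'
#' @param tg_images,wt_images lists of [image_volume()] on one grid,
#'   previously reference-scaled.
#' @param mask logical brain mask on the same grid.
#' @param alternative `"greater"` (default, TG > WT) or `"two.sided"`.
#' @param tracer,age_months optional metadata carried on the result.
#' @return an object of class `t_score_map`: arrays `t` and `p` (NA outside
#'   the mask), `df`, `mask`, `n_per_group`, `tracer`, `age_months`.
#' @export
voxelwise_ttest <- function(tg_images, wt_images, mask,
                            alternative = c("greater", "two.sided"),
                            tracer = NA_character_, age_months = NA_real_) {
  alternative <- match.arg(alternative)
  n1 <- length(tg_images)
  n2 <- length(wt_images)
  assert_that(n1 == n2, "unequal group sizes (%d vs %d): the design requires equal groups",
              n1, n2)
  assert_that(n1 >= 2, "need at least 2 images per group")
  grid <- tg_images[[1]]$grid
  for (img in c(tg_images, wt_images)) {
    assert_that(inherits(img, "image_volume"), "inputs must be image_volume")
    assert_that(same_grid(img$grid, grid), "images are on mismatched grids")
  }
  assert_that(is.logical(mask) && identical(dim(mask), dim(tg_images[[1]]$data)),
              "mask must be a logical array on the image grid")
  assert_that(any(mask), "brain mask is empty")

  X <- vapply(tg_images, function(im) im$data[mask], numeric(sum(mask)))
  Y <- vapply(wt_images, function(im) im$data[mask], numeric(sum(mask)))
  m1 <- rowMeans(X)
  m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tvals <- (m1 - m2) / se
  degenerate <- se == 0
  if (any(degenerate)) {
    tvals[degenerate] <- 0
    message(sprintf("voxelwise_ttest: %d voxel(s) with zero pooled variance set to t = 0, p = 1",
                    sum(degenerate)))
  }
  pvals <- if (alternative == "greater") {
    pt(tvals, df, lower.tail = FALSE)
  } else {
    2 * pt(abs(tvals), df, lower.tail = FALSE)
  }
  pvals[degenerate] <- 1

  tmap <- array(NA_real_, dim = dim(mask))
  pmap <- array(NA_real_, dim = dim(mask))
  tmap[mask] <- tvals
  pmap[mask] <- pvals
  structure(list(t = tmap, p = pmap, df = df, mask = mask, grid = grid,
                 n_per_group = n1, alternative = alternative,
                 tracer = tracer, age_months = age_months),
            class = "t_score_map")
}

#' @export
print.t_score_map <- function(x, ...) {
  cat(sprintf("<t_score_map> df=%d, %d masked voxels, t range [%.2f, %.2f]%s\n",
              x$df, sum(x$mask), min(x$t[x$mask]), max(x$t[x$mask]),
              if (!is.na(x$tracer)) sprintf(" [%s, %g mo]", x$tracer,
                                            x$age_months) else ""))
  invisible(x)
}

#' FDR-threshold and binarize a t-score map
#'
#' Benjamini-Hochberg step-up over the p-values of all brain-mask voxels at
#' level `q`; the rejection set is converted to the equivalent t-score
#' threshold (the smallest t among rejected voxels, `+Inf` when nothing is
#' rejected) and the map binarized: 1 = significantly elevated versus
#' wild-type, 0 = not.
#'
#' @param tmap a `t_score_map` from [voxelwise_ttest()].
#' @param q nominal FDR level in (0, 1).
#' @return an object of class `binary_map`: logical array `elevated`
#'   (a subset of the mask), `t_threshold`, `q`, `n_significant`, `mask`.
#' @export
fdr_binarize <- function(tmap, q = 0.05) {
  assert_that(inherits(tmap, "t_score_map"), "tmap must be a t_score_map")
  assert_that(is.numeric(q) && length(q) == 1 && q > 0 && q < 1,
              "q must be in (0, 1)")
  p <- tmap$p[tmap$mask]
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  elevated <- array(FALSE, dim = dim(tmap$mask))
  if (length(below) == 0) {
    t_threshold <- Inf
  } else {
    pcrit <- ps[max(below)]
    rej <- p <= pcrit  # step-up: everything at or below the largest passing p
    t_threshold <- min(tmap$t[tmap$mask][rej])
    elevated[tmap$mask] <- rej
  }
  structure(list(elevated = elevated, t_threshold = t_threshold, q = q,
                 n_significant = sum(elevated), mask = tmap$mask,
                 grid = tmap$grid, df = tmap$df, tracer = tmap$tracer,
                 age_months = tmap$age_months),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> q=%g, t_threshold=%.3g, %d/%d voxels elevated\n",
              x$q, x$t_threshold, x$n_significant, sum(x$mask)))
  invisible(x)
}
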