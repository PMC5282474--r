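# Shared fixtures, built in code. The default atlas is cached per session
# because several test files need it.
.fixtures <- new.env(parent = emptyenv())

test_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- build_atlas()
  .fixtures$atlas
}

# quiet parameter sets
params_noiseless <- function(...) pathology_params(noise_sd = 0, ...)

# parameters with all transgenic pathology amplitudes zeroed: TG and WT
# cohorts become exchangeable (the null generator)
params_null <- function(...) {
  base <- pathology_params()
  pathology_params(
    amyloid_region_amp = setNames(rep(0, length(base$amyloid_region_amp)),
                                  names(base$amyloid_region_amp)),
    diffuse_region_weight = setNames(rep(0, length(base$diffuse_region_weight)),
                                     names(base$diffuse_region_weight)),
    ...
  )
}

# construct a t_score_map directly from vectors of t (and optionally p)
# values over an arbitrary small mask, for unit tests of the downstream
# operations
synth_tmap <- function(tvals, pvals = NULL, df = 14L,
                       dims = c(length(tvals), 1L, 1L),
                       mask = NULL, tracer = NA_character_,
                       age_months = NA_real_) {
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  stopifnot(sum(mask) == length(tvals))
  tarr <- array(NA_real_, dim = dims)
  parr <- array(NA_real_, dim = dims)
  tarr[mask] <- tvals
  if (is.null(pvals)) pvals <- pt(tvals, df, lower.tail = FALSE)
  parr[mask] <- pvals
  structure(list(t = tarr, p = parr, df = df, mask = mask,
                 grid = grid_spec(dims, c(1, 1, 1)),
                 n_per_group = df / 2 + 1, alternative = "greater",
                 tracer = tracer, age_months = age_months),
            class = "t_score_map")
}

synth_binmap <- function(elevated, mask = NULL, q = 0.05,
                         t_threshold = 2, age_months = NA_real_) {
  elevated <- as.array(elevated)
  if (is.null(dim(elevated)) || length(dim(elevated)) != 3) {
    elevated <- array(elevated, dim = c(length(elevated), 1L, 1L))
  }
  if (is.null(mask)) mask <- array(TRUE, dim = dim(elevated))
  structure(list(elevated = elevated & mask, t_threshold = t_threshold,
                 q = q, n_significant = sum(elevated & mask), mask = mask,
                 grid = grid_spec(dim(elevated), c(1, 1, 1)), df = 14L,
                 tracer = NA_character_, age_months = age_months),
            class = "binary_map")
}

# random image list on a small grid (for voxel-stat oracles)
random_images <- function(n, dims = c(10, 10, 5), mu = 0, sd = 1) {
  g <- grid_spec(dims, c(0.5, 0.5, 0.5))
  lapply(seq_len(n), function(i)
    image_volume(array(rnorm(prod(dims), mu, sd), dim = dims), g))
}

# quadratic-time reference implementation of Benjamini-Hochberg step-up:
# for every p, reject iff there exists a p' >= p whose rank-threshold test
# passes. Independent of the production code path.
bh_reference <- function(p, q) {
  m <- length(p)
  rej <- logical(m)
  ps <- sort(p)
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  if (kmax > 0) rej <- p <= ps[kmax]
  rej
}
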