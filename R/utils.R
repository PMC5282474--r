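`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dualpet <- function(fmt, ..., class = "dualpet_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "dualpet_error")))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_dualpet(fmt, ...)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so simulation functions do not disturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic integer mixer used to derive independent substream seeds from
# a master seed plus identifying integer components (genotype code, age,
# replicate, purpose). All arithmetic stays below 2^53 so doubles are exact;
# the result is in [1, 2^31 - 2] and valid for set.seed().
mix_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (c in as.numeric(c(...))) {
    h <- (h * 48271 + c + 11) %% m
    h <- (h * 69621 + 7) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used to fingerprint resolved pipeline configurations in reports.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# genotype / tracer code books used for seed derivation and validation
.genotypes <- c(TG = 1L, WT = 2L)
.tracers <- c(tspo = 1L, amyloid = 2L)

check_genotype <- function(genotype) {
  assert_that(is.character(genotype) && length(genotype) == 1 &&
                genotype %in% names(.genotypes),
              "unknown genotype '%s' (expected one of: %s)",
              paste(genotype, collapse = ","),
              paste(names(.genotypes), collapse = ", "))
  genotype
}

check_tracer <- function(tracer) {
  assert_that(is.character(tracer) && length(tracer) == 1 &&
                tracer %in% names(.tracers),
              "unknown tracer '%s' (expected one of: %s)",
              paste(tracer, collapse = ","),
              paste(names(.tracers), collapse = ", "))
  tracer
}
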