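# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream; a NULL seed uses (and advances) the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation (replicate streams, stage seeds); kept
# below 2^31 so the result is a valid integer seed.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

PROTON_MASS <- 1.00728
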