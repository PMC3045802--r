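# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-replicate seed from a master seed
#'
#' Deterministic derivation so any single replicate of a seeded experiment can
#' be regenerated in isolation. Kept below 2^31 - 1 so the result is always a
#' valid R integer seed.
#'
#' @param master integer master seed.
#' @param i replicate index (positive integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, i) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(i))
  as.integer((abs(as.numeric(master)) * 7919 + as.numeric(i) * 104729) %%
               2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# stats::median as a bare numeric (drops names)
med3 <- function(x) {
  c(median = stats::median(x), min = min(x), max = max(x))
}
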