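# Seed scoping: evaluate an expression under a fixed RNG state, restoring
# the caller's stream afterwards so that library code never perturbs user
# simulations. seed = NULL uses (and advances) the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Independent sub-seeds derived from a master seed (kept below 2^31).
.derive_seeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

.round_half_up <- function(x) floor(x + 0.5)  # round half away from zero (x >= 0 here)
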