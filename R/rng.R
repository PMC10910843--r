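#' Derive a stream-specific seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single integer master seed, split per named sub-generator.  The split is a
#' small deterministic hash, so that the phantom produced for one stage does
#' not change when another stage is added, removed or reordered.
#'
#' @param seed master integer seed.
#' @param stream character tag naming the consumer (e.g. `"dwi"`, `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 31 + ch) %% m
  as.integer(((abs(seed) %% m) * 69069 + h) %% m)
}

# run expr with a locally-set RNG state, restoring the caller's state
with_stream_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}
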