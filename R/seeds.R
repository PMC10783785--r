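#' Derive a named substream seed from a master seed
#'
#' Every stochastic stage of the pipeline (nucleus placement, stain noise,
#' expression draws, survival times, block/nucleus sampling, CV folds,
#' train/test splits, permutations) draws its randomness from a named
#' substream of a single master seed, so any stage can be regenerated
#' independently of the others.
#'
#' The substream seed is a deterministic 31-bit hash of the master seed and
#' the stream name (polynomial string hash combined with a multiplicative
#' mix). Distinct names give effectively independent `set.seed()` states.
#'
#' @param seed master integer seed.
#' @param name character stream name, e.g. `"placement"`, `"cv-folds"`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  out <- (s * 48271 + h * 16807 + 12345) %% m
  as.integer(if (out == 0) 1 else out)
}

# Run `expr` with the RNG seeded from a named substream, restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}
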