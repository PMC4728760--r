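#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' Named substreams keep the random draws of unrelated simulation components
#' independent: changing, say, the residual draws of a scenario never perturbs
#' the clinic sizes, and adding a sweep parameter leaves all other streams
#' untouched. The label is hashed with a 31-ary polynomial rolling hash modulo
#' the Mersenne prime 2^31 - 1 and folded into the base seed.
#'
#' @param seed Integer base seed.
#' @param stream Character scalar naming the stream (e.g. `"sizes"`).
#' @return A single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(42L, "sizes")
#' substream_seed(42L, "residuals")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% m
  }
  # fold in the base seed; keep strictly below 2^31 so set.seed() is happy
  as.integer((abs(seed) %% m + h * 2654435.0) %% m)
}

# Run `expr` under a seeded RNG state, restoring the caller's state after.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}
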