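#' Derive a reproducible sub-seed
#'
#' Maps a base seed and a stream index to a new 32-bit seed via a
#' minimal-standard LCG step. Used throughout the package so that per-plot
#' and per-stage random draws are independent of evaluation order while
#' remaining governed by a single top-level seed.
#'
#' @param seed integer base seed.
#' @param stream nonnegative integer stream index.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647
  s <- as.double(seed) %% m
  # 48271 * (m - 1) < 2^53, so double arithmetic is exact here
  s <- (s * 48271) %% m
  s <- (s + (as.double(stream) %% m) * 104729) %% m
  as.integer(s)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# scalar checks used across modules
assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}
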