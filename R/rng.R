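# Reproducibility helpers: every stochastic routine draws from its own
# seeded stream so that runs replay exactly and never disturb the caller's
# global RNG state.

#' Derive a deterministic sub-stream seed
#'
#' Mixes a root seed with a stream label so that independent stages of a run
#' (splitting, fold assignment, optimizer, controller) each get their own
#' reproducible stream. Results stay within the 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param stream non-negative integer stream label.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stream) {
  m <- 2147483647           # 2^31 - 1, Mersenne prime modulus
  s <- (as.double(seed) %% m) * 48271 + as.double(stream) * 16807 + 12345
  as.integer(s %% m)
}

# A self-contained RNG stream: draws are taken under a private .Random.seed,
# leaving the global RNG untouched.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed))
    else assign(".Random.seed", state, envir = globalenv())
    res <- expr
    state <<- get(".Random.seed", envir = globalenv())
    if (had_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = n, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    sample_perm = function(n) with_state(sample.int(n))
  )
}
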