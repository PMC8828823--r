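# Local RNG streams.
#
# Every stochastic operation in the package draws from an explicit stream
# created from an integer seed, so results are reproducible and independent
# of (and invisible to) the caller's global RNG state.

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_global_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

make_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  env <- new.env(parent = emptyenv())
  old <- get_global_seed()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get_global_seed()
  restore_global_seed(old)
  env
}

with_rng <- function(rng, expr) {
  old <- get_global_seed()
  restore_global_seed(rng$state)
  res <- force(expr)
  rng$state <- get_global_seed()
  restore_global_seed(old)
  res
}

rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, sample(x, size = size, replace = replace))
}
rng_runif <- function(rng, n, min = 0, max = 1) with_rng(rng, runif(n, min, max))
rng_rnorm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, rnorm(n, mean, sd))
rng_rpois <- function(rng, n, lambda) with_rng(rng, rpois(n, lambda))
rng_rlnorm <- function(rng, n, meanlog, sdlog) with_rng(rng, rlnorm(n, meanlog, sdlog))
rng_rint <- function(rng, n, max) with_rng(rng, sample.int(max, n, replace = TRUE))
# derive a child stream (e.g. one per study) from a parent stream
rng_spawn <- function(rng) {
  make_rng(with_rng(rng, sample.int(.Machine$integer.max - 1L, 1L)))
}
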