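# Self-contained random streams. Each generator owns its own Mersenne-Twister
# state so that simulation draws are reproducible per subject and never
# disturb (or depend on) the caller's global .Random.seed.

new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% 2147483647L, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

runif_rng <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))

rnorm_rng <- function(rng, n, mean = 0, sd = 1)
  with_rng(rng, stats::rnorm(n, mean, sd))

sample_rng <- function(rng, x)
  with_rng(rng, sample(x, length(x), replace = FALSE))
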