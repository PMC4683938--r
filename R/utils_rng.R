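# Seeded random-number stream that does not disturb the caller's RNG.
# Every stochastic operation in the package draws through one of these,
# created from an explicit integer seed, so runs are bit-reproducible and
# independent of global .Random.seed.
new_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(old)) rm(".Random.seed", envir = genv)
  else assign(".Random.seed", old, envir = genv)

  draw <- function(expr) {
    old <- get0(".Random.seed", envir = genv, inherits = FALSE)
    assign(".Random.seed", env$state, envir = genv)
    on.exit({
      env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
      if (is.null(old)) rm(".Random.seed", envir = genv)
      else assign(".Random.seed", old, envir = genv)
    })
    expr
  }
  env$draw <- draw
  env$runif <- function(n, ...) draw(stats::runif(n, ...))
  env$rbinom <- function(n, size, prob) draw(stats::rbinom(n, size, prob))
  env$rbeta <- function(n, a, b) draw(stats::rbeta(n, a, b))
  env$sample_int <- function(n, size, replace = FALSE)
    draw(sample.int(n, size, replace = replace))
  env$resample <- function(n) draw(sample.int(n, n, replace = TRUE))
  env$permute <- function(n) draw(sample.int(n, n, replace = FALSE))
  # derive a fresh child seed (kept below 2^31)
  env$spawn_seed <- function() draw(sample.int(.Machine$integer.max, 1L))
  env
}
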