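# Seeded RNG helper: an isolated random stream that does not disturb (and is
# not disturbed by) the caller's global RNG state. Every stochastic operation
# in the package draws from one of these, so results are pure functions of
# (inputs, seed).

local_rng <- function(seed) {
  state <- NULL
  with_state <- function(expr) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(state)) set.seed(as.integer(seed)) else
      assign(".Random.seed", state, envir = globalenv())
    res <- expr
    state <<- get(".Random.seed", envir = globalenv())
    res
  }
  list(
    # permutation of 1..n
    sample_idx = function(n) with_state(sample.int(n)),
    # one uniform integer in 1..n
    draw_int = function(n) with_state(sample.int(n, 1L)),
    # k draws (with or without replacement) from 1..n, optional prob weights
    draw = function(n, k, replace = FALSE, prob = NULL)
      with_state(sample.int(n, k, replace = replace, prob = prob)),
    runif = function(k) with_state(stats::runif(k)),
    rpois = function(k, lambda) with_state(stats::rpois(k, lambda)),
    rbinom = function(k, size, p) with_state(stats::rbinom(k, size, p)),
    rnorm = function(k, mean = 0, sd = 1)
      with_state(stats::rnorm(k, mean, sd)),
    # derive a child seed (kept below 2^31)
    child_seed = function() with_state(sample.int(.Machine$integer.max, 1L))
  )
}

# Evaluate expr under a temporary global seed, restoring previous RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
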