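# A small self-contained RNG stream: seeded draws that neither read nor
# disturb the caller's .Random.seed. Each draw swaps the stream's state into
# the global RNG, draws, and swaps the previous state back.

local_rng <- function(seed) {
  state <- NULL
  swap_in <- function() {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    if (is.null(state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    old
  }
  swap_out <- function(old) {
    state <<- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  with_state <- function(f) {
    old <- swap_in()
    on.exit(swap_out(old))
    f()
  }
  list(
    sample_int = function(n, size, replace = FALSE) {
      with_state(function() sample.int(n, size, replace = replace))
    },
    sample = function(x, size, replace = FALSE) {
      with_state(function() sample(x, size, replace = replace))
    },
    runif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() rnorm(n, mean, sd)),
    rbinom = function(n, size, prob) with_state(function() rbinom(n, size, prob)),
    rgeom = function(n, prob) with_state(function() stats::rgeom(n, prob)),
    spawn_seed = function() {
      with_state(function() sample.int(.Machine$integer.max %/% 2L, 1L))
    }
  )
}
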