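# Seeded RNG scoped to one annotation run, isolated from the caller's
# global random state so pipeline results never depend on what the session
# did before.

make_rng <- function(seed) {
  state <- local({
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    get(".Random.seed", envir = globalenv())
  })
  draw <- function(expr_fun) {
    old <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(
    # uniform integer in [lo, hi], inclusive
    int_in = function(lo, hi) draw(function() {
      as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
    }),
    sample_without_replacement = function(x, k) draw(function() {
      x[sample.int(length(x), k)]
    }),
    unif = function(n = 1) draw(function() stats::runif(n))
  )
}
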