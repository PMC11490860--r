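# Shared memoised solves so that expensive boundary-value solutions are
# computed once per test run and reused across test files.

.solve_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .solve_cache, inherits = FALSE))
    assign(key, force(expr), envir = .solve_cache)
  get(key, envir = .solve_cache, inherits = FALSE)
}

baseline_solution <- function() {
  cached("baseline", {
    p <- model_params()
    solve_station(station(0, p), p, solver_options())
  })
}

# numerical directional-derivative check utility
num_jac_col <- function(f, x, j, h = 1e-6) {
  xp <- x; xp[j] <- xp[j] + h
  xm <- x; xm[j] <- xm[j] - h
  (f(xp) - f(xm)) / (2 * h)
}
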