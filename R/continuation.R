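#' Parameter-continuation solve
#'
#' Ramps the parameters named in \code{ramp} linearly from easy starting
#' values (0 for the stiffness-driving groups \code{M}, \code{Br},
#' \code{Gr}, \code{Gm}, \code{k}; the target value for anything else)
#' up to their targets, warm-starting each solve from the previous one.
#' With \code{steps = 1} this is identical to a direct solve.
#'
#' @param st a \code{\link{station}}.
#' @param target_params the (admissible) \code{model_params} to reach.
#' @param opts a \code{\link{solver_options}} object.
#' @param ramp character vector of parameter names to ramp
#'   (default \code{c("M", "Br", "Gr", "Gm", "k")}).
#' @param steps number of ramp increments (default 4); on failure the
#'   schedule is refined (doubled) up to \code{max_steps}.
#' @param max_steps cap on schedule refinement (default 32).
#' @return A converged \code{solution_field} at the target parameters.
#' @export
continuation_solve <- function(st, target_params, opts = solver_options(),
                               ramp = c("M", "Br", "Gr", "Gm", "k"),
                               steps = 4L, max_steps = 32L) {
  validate_params(target_params)
  easy_value <- function(name) {
    if (name %in% c("M", "Br", "Gr", "Gm", "k", "Nt", "alpha")) 0
    else target_params[[name]]
  }
  while (steps <= max_steps) {
    sol <- NULL
    failed <- FALSE
    ts <- seq_len(steps) / steps
    for (tt in ts) {
      p <- target_params
      for (nm in ramp)
        p[[nm]] <- easy_value(nm) + tt * (target_params[[nm]] - easy_value(nm))
      sol_t <- tryCatch(
        solve_station(st, p, opts, init = sol),
        ciliaflow_convergence_error = function(e) NULL)
      if (is.null(sol_t)) { failed <- TRUE; break }
      sol <- sol_t
    }
    if (!failed) return(sol)
    steps <- steps * 2L
  }
  cond <- structure(
    class = c("ciliaflow_convergence_error", "error", "condition"),
    list(message = sprintf(
      "continuation exhausted its ramp schedule (up to %d steps)", max_steps),
      call = NULL, last = NULL, history = NULL))
  stop(cond)
}

#' Solve with automatic continuation fallback
#'
#' Attempts a direct solve; on a convergence failure retries with
#' \code{\link{continuation_solve}}.
#'
#' @inheritParams continuation_solve
#' @param params target \code{model_params}.
#' @param init optional warm-start \code{solution_field}.
#' @return A converged \code{solution_field}.
#' @export
robust_solve <- function(st, params, opts = solver_options(), init = NULL) {
  tryCatch(
    solve_station(st, params, opts, init = init),
    ciliaflow_convergence_error = function(e)
      continuation_solve(st, params, opts))
}
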