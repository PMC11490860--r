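#' Solver options
#'
#' Numerical controls shared by the three boundary-value solvers.
#'
#' @param tolerance maximum permitted combined boundary-condition and ODE
#'   residual for a solution to count as converged. Default \code{1e-8}
#'   (two digits of headroom over the \code{1e-6} checks downstream).
#' @param max_mesh cap on the adaptive mesh size.
#' @param initial_mesh_n starting node count.
#' @param method \code{"collocation"} (default), \code{"shooting"} or
#'   \code{"finite_difference"}.
#' @param seed integer seed for any randomised perturbation of initial
#'   guesses (the default algorithms are fully deterministic; the seed is
#'   recorded for provenance).
#' @return An object of class \code{"solver_options"}.
#' @export
solver_options <- function(tolerance = 1e-8, max_mesh = 10000L,
                           initial_mesh_n = 51L,
                           method = c("collocation", "shooting",
                                      "finite_difference"),
                           seed = 0L) {
  stopifnot(tolerance > 0, initial_mesh_n >= 5L,
            max_mesh >= initial_mesh_n)
  o <- list(tolerance = tolerance, max_mesh = as.integer(max_mesh),
            initial_mesh_n = as.integer(initial_mesh_n),
            method = match.arg(method), seed = as.integer(seed))
  class(o) <- "solver_options"
  o
}

# Construct a solution_field object. states: n x 10 matrix (rows = nodes).
new_solution_field <- function(st, params, y_grid, states, converged,
                               residual_norm, method, iterations = NA_integer_) {
  colnames(states) <- STATE_NAMES
  sol <- list(station = st, params = params, y_grid = y_grid,
              states = states, converged = converged,
              residual_norm = residual_norm, mesh_n = length(y_grid),
              method = method, iterations = iterations)
  class(sol) <- "solution_field"
  sol
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(
    "Solution field (%s) at x = %g: %d nodes on [%.4g, %.4g], %s (residual %.3g)\n",
    x$method, x$station$x, x$mesh_n, x$y_grid[1L],
    x$y_grid[x$mesh_n], if (x$converged) "converged" else "NOT converged",
    x$residual_norm))
  invisible(x)
}

#' Boundary-consistent initial guess
#'
#' Seeds the solvers with fields that satisfy all ten boundary conditions
#' exactly: \eqn{\psi} is the unique cubic matching \eqn{\psi = \mp q/2} and
#' \eqn{\psi' = u_o} at the walls, \eqn{\theta} and \eqn{\Omega} are linear
#' between their wall values, and \eqn{w \equiv 0}; derivative components
#' are consistent with those fields.
#'
#' @param st a \code{\link{station}}.
#' @param params a \code{model_params} object.
#' @param n node count (>= 5); nodes are uniform on \code{[h2, h1]}.
#' @return An (unconverged) \code{solution_field}.
#' @export
initial_guess <- function(st, params, n = 51L) {
  stopifnot(n >= 5L)
  validate_params(params)
  y <- seq(st$h2, st$h1, length.out = n)
  guess_states(st, params, y)
}

# states on an arbitrary grid; shared with continuation restarts
guess_states <- function(st, params, y) {
  n <- length(y)
  h1 <- st$h1; h2 <- st$h2; H <- h1 - h2
  # cubic psi(t) = c0 + c1 t + c2 t^2 + c3 t^3 on t = y - h2 with
  # psi(0) = -q/2, psi'(0) = uo, psi(H) = q/2, psi'(H) = uo
  q <- params$q; uo <- st$uo
  c0 <- -q / 2; c1 <- uo
  # psi(H): c0 + c1 H + c2 H^2 + c3 H^3 = q/2
  # psi'(H): c1 + 2 c2 H + 3 c3 H^2 = uo
  rhs1 <- q / 2 - c0 - c1 * H
  c2 <- 3 * rhs1 / H^2          # from solving the 2x2 system (rhs2 = 0)
  c3 <- -2 * rhs1 / H^3
  t <- y - h2
  wv <- bc_wall_values(params)
  th_lo <- wv$lower[1L]; th_hi <- wv$upper[1L]
  om_lo <- wv$lower[2L]; om_hi <- wv$upper[2L]
  S <- matrix(0, nrow = n, ncol = 10L)
  S[, 1L] <- c0 + c1 * t + c2 * t^2 + c3 * t^3
  S[, 2L] <- c1 + 2 * c2 * t + 3 * c3 * t^2
  S[, 3L] <- 2 * c2 + 6 * c3 * t
  S[, 4L] <- 6 * c3
  S[, 5L] <- th_lo + (th_hi - th_lo) * t / H
  S[, 6L] <- (th_hi - th_lo) / H
  S[, 7L] <- om_lo + (om_hi - om_lo) * t / H
  S[, 8L] <- (om_hi - om_lo) / H
  new_solution_field(st, params, y, S, converged = FALSE,
                     residual_norm = Inf, method = "initial_guess")
}
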