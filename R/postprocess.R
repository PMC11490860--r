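#' Interpolate a solution field onto arbitrary points
#'
#' Componentwise cubic-spline interpolation of all ten state components.
#' Used for cross-solver comparison and symmetry checks; the interpolation
#' error is far below the solver tolerances for converged meshes.
#'
#' @param sol a \code{solution_field}.
#' @param y numeric vector of transverse positions within
#'   \code{[h2, h1]}.
#' @return A \code{length(y)} x 10 matrix of states (columns named as in
#'   the solution field).
#' @export
interpolate_solution <- function(sol, y) {
  S <- vapply(seq_len(10L), function(j)
    stats::spline(sol$y_grid, sol$states[, j], xout = y,
                  method = "fmm")$y,
    numeric(length(y)))
  S <- matrix(S, nrow = length(y))
  colnames(S) <- STATE_NAMES
  S
}

stop_if_unconverged <- function(sol, what) {
  if (!isTRUE(sol$converged))
    stop(what, " requires a converged solution field", call. = FALSE)
}

#' Wall fluxes: skin friction, Nusselt and Sherwood numbers
#'
#' Evaluates at both walls
#' \deqn{C_f = \frac{1}{1+\lambda_1}\left.\frac{\partial u}{\partial y}\right|_{h_1,h_2},
#'       \quad Nu = -\left.\frac{\partial\theta}{\partial y}\right|_{h_1,h_2},
#'       \quad Sh = -\left.\frac{\partial\Omega}{\partial y}\right|_{h_1,h_2}.}
#' Derivatives are read from the solved state components at the end nodes
#' (\eqn{\psi''}, \eqn{\theta'}, \eqn{\Omega'}), not re-differenced. The raw
#' \eqn{-\partial/\partial y} sign is reported at both walls (no
#' outward-normal flip); see \code{outward = TRUE} for the outward-normal
#' convention.
#'
#' @param sol a converged \code{solution_field}.
#' @param params a \code{model_params} object.
#' @param outward if \code{TRUE}, flip the sign of Nu and Sh at the lower
#'   wall so both walls report the flux along the outward normal.
#' @return An object of class \code{"wall_fluxes"}: list with
#'   \code{cf_h1, cf_h2, nu_h1, nu_h2, sh_h1, sh_h2}.
#' @export
wall_fluxes <- function(sol, params, outward = FALSE) {
  stop_if_unconverged(sol, "wall_fluxes")
  n <- sol$mesh_n
  lo <- sol$states[1L, ]; hi <- sol$states[n, ]
  sgn <- if (outward) -1 else 1
  wf <- list(cf_h1 = hi[["d2psi"]] / (1 + params$lambda1),
             cf_h2 = lo[["d2psi"]] / (1 + params$lambda1),
             nu_h1 = -hi[["dtheta"]],
             nu_h2 = sgn * -lo[["dtheta"]],
             sh_h1 = -hi[["domega"]],
             sh_h2 = sgn * -lo[["domega"]])
  class(wf) <- "wall_fluxes"
  wf
}

#' @export
print.wall_fluxes <- function(x, ...) {
  cat(sprintf("Wall fluxes:  Cf(h1) = %.6g  Cf(h2) = %.6g\n",
              x$cf_h1, x$cf_h2))
  cat(sprintf("              Nu(h1) = %.6g  Nu(h2) = %.6g\n",
              x$nu_h1, x$nu_h2))
  cat(sprintf("              Sh(h1) = %.6g  Sh(h2) = %.6g\n",
              x$sh_h1, x$sh_h2))
  invisible(x)
}

#' Axial pressure gradient with constancy audit
#'
#' The lubrication limit makes the pressure independent of \eqn{y}
#' (\eqn{\partial p/\partial y = 0}), so the pointwise evaluation of the
#' momentum balance
#' \deqn{\frac{dp}{dx} = \frac{u''}{1+\lambda_1} + Gr\,\theta + Gm\,\Omega
#'       - \left(M^2 + \frac{1}{Da}\right)(u+1) + \frac{k}{\mu} w'}
#' must be constant across the channel for the true solution. The mean over
#' the mesh is the reported gradient; the maximum deviation from the mean
#' audits the solve.
#'
#' @param sol a converged \code{solution_field}.
#' @param params a \code{model_params} object.
#' @param per_node if \code{TRUE}, include the per-node values.
#' @return An object of class \code{"pressure_gradient"}: list with
#'   \code{dpdx_mean}, \code{dpdx_dev} (max absolute deviation from the
#'   mean) and optionally \code{per_node} (data frame \code{y, dpdx}).
#' @export
pressure_gradient <- function(sol, params, per_node = FALSE) {
  stop_if_unconverged(sol, "pressure_gradient")
  S <- sol$states
  dpdx <- S[, "d3psi"] / (1 + params$lambda1) +
    params$Gr * S[, "theta"] + params$Gm * S[, "omega"] -
    (params$M^2 + 1 / params$Da) * (S[, "u"] + 1) +
    (params$k / params$mu) * S[, "dw"]
  res <- list(dpdx_mean = mean(dpdx), dpdx_dev = max(abs(dpdx - mean(dpdx))))
  if (per_node) res$per_node <- data.frame(y = sol$y_grid, dpdx = dpdx)
  class(res) <- "pressure_gradient"
  res
}

#' @export
print.pressure_gradient <- function(x, ...) {
  cat(sprintf("dp/dx = %.8g (max deviation over mesh %.3g)\n",
              x$dpdx_mean, x$dpdx_dev))
  invisible(x)
}

# Cubic-Hermite quadrature of u = psi' using the in-state derivative psi''
# (fourth-order accurate on each interval).
flux_quadrature <- function(sol) {
  y <- sol$y_grid
  u <- sol$states[, "u"]; du <- sol$states[, "d2psi"]
  h <- diff(y)
  n <- length(y)
  sum(h / 2 * (u[-n] + u[-1L]) + h^2 / 12 * (du[-n] - du[-1L]))
}

#' Audit the exact model invariants of a solution
#'
#' Three checks that the continuous model satisfies exactly:
#' \enumerate{
#'   \item the concentration equation integrates twice to
#'     \eqn{\Omega + (Nt/Nb)\,\theta} linear in \eqn{y}; reported is the
#'     maximum deviation from the least-squares line;
#'   \item flux conservation \eqn{\int u\,dy = q}, reported both as the
#'     exact stream-function jump \eqn{|\psi(h_1)-\psi(h_2)-q|} and as a
#'     cubic-Hermite quadrature of \eqn{u};
#'   \item the maximum of the ten boundary-condition residuals.
#' }
#'
#' @param sol a converged \code{solution_field}.
#' @param params a \code{model_params} object.
#' @return List with \code{first_integral_dev}, \code{flux_err}
#'   (stream-function jump), \code{flux_quad_err} (quadrature) and
#'   \code{max_bc_residual}.
#' @export
invariant_audit <- function(sol, params) {
  y <- sol$y_grid
  rat <- if (params$Nb > 0) params$Nt / params$Nb else 0
  z <- sol$states[, "omega"] + rat * sol$states[, "theta"]
  fit <- stats::lm.fit(cbind(1, y), z)
  dev1 <- max(abs(fit$residuals))
  st <- sol$station
  flux_err <- abs(unname(sol$states[sol$mesh_n, "psi"] -
                           sol$states[1L, "psi"]) - params$q)
  quad_err <- abs(flux_quadrature(sol) - params$q)
  bc <- bc_residuals(sol$states[1L, ], sol$states[sol$mesh_n, ], st, params)
  list(first_integral_dev = dev1, flux_err = flux_err,
       flux_quad_err = quad_err, max_bc_residual = max(abs(bc)))
}

#' Centre-line values of the solved fields
#'
#' Cubic (four-nearest-node Lagrange) interpolation of the axial velocity,
#' temperature, concentration and microrotation at the channel midline
#' \eqn{y = (h_1 + h_2)/2}.
#'
#' @param sol a converged \code{solution_field}.
#' @return Named numeric vector \code{c(u, theta, omega, w)}.
#' @export
center_values <- function(sol) {
  stop_if_unconverged(sol, "center_values")
  yc <- (sol$station$h1 + sol$station$h2) / 2
  y <- sol$y_grid
  i <- findInterval(yc, y)
  j0 <- min(max(i - 1L, 1L), length(y) - 3L)
  idx <- j0:(j0 + 3L)
  w <- vapply(idx, function(j)
    prod((yc - y[setdiff(idx, j)]) / (y[j] - y[setdiff(idx, j)])),
    numeric(1L))
  vals <- drop(w %*% sol$states[idx, c("u", "theta", "omega", "w")])
  names(vals) <- c("u", "theta", "omega", "w")
  vals
}
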