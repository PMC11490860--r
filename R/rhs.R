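# Reduced first-order system.
#
# State components (all dimensionless, functions of the transverse
# coordinate y):
#   xi1 = psi      stream function          xi2 = psi'  (= axial velocity u)
#   xi3 = psi''                             xi4 = psi'''
#   xi5 = theta    temperature              xi6 = theta'
#   xi7 = Omega    nanoparticle conc.       xi8 = Omega'
#   xi9 = w        microrotation            xi10 = w'
#
# Closures:
#   xi10' = (k d1/gamma1) (2 xi9 + xi3)                        [spin transport]
#   xi4'  = (1+lambda1) [ -Gr xi6 - Gm xi8 + (M^2 + 1/Da) xi3
#                         - (k/mu) xi10' ]                     [momentum, d/dy]
#   xi6'  = -Br ( xi3^2/(1+lambda1) + M^2 (xi2+1)^2 )
#           - Pr Nb xi8 xi6 - Nt Pr xi6^2                      [energy]
#   xi8'  = -(Nt/Nb) xi6'                                      [concentration]
# The Joule-heating argument (xi2+1) switches to (xi3+1) under
# joule_variant = "shear".

STATE_NAMES <- c("psi", "u", "d2psi", "d3psi", "theta", "dtheta",
                 "omega", "domega", "w", "dw")

# Vectorised RHS: S is a 10 x n matrix of states, returns 10 x n derivatives.
rhs_mat <- function(S, params) {
  p <- params
  c1 <- p$k * p$d1 / p$gamma1
  A1 <- 1 + p$lambda1
  beta <- p$M^2 + 1 / p$Da
  r10 <- c1 * (2 * S[9L, ] + S[3L, ])
  r4 <- A1 * (-p$Gr * S[6L, ] - p$Gm * S[8L, ] + beta * S[3L, ] -
                (p$k / p$mu) * r10)
  up <- if (p$joule_variant == "velocity") S[2L, ] + 1 else S[3L, ] + 1
  r6 <- -p$Br * (S[3L, ]^2 / A1 + p$M^2 * up^2) -
    p$Pr * p$Nb * S[8L, ] * S[6L, ] - p$Nt * p$Pr * S[6L, ]^2
  r8 <- if (p$Nb > 0) -(p$Nt / p$Nb) * r6 else rep(0, ncol(S))
  rbind(S[2L, ], S[3L, ], S[4L, ], r4, S[6L, ], r6, S[8L, ], r8,
        S[10L, ], r10, deparse.level = 0L)
}

# Jacobian of the RHS at each column of S: 10 x 10 x n array.
rhs_jac <- function(S, params) {
  p <- params
  n <- ncol(S)
  c1 <- p$k * p$d1 / p$gamma1
  A1 <- 1 + p$lambda1
  beta <- p$M^2 + 1 / p$Da
  J <- array(0, dim = c(10L, 10L, n))
  J[1L, 2L, ] <- 1
  J[2L, 3L, ] <- 1
  J[3L, 4L, ] <- 1
  J[4L, 3L, ] <- A1 * (beta - (p$k / p$mu) * c1)
  J[4L, 6L, ] <- -A1 * p$Gr
  J[4L, 8L, ] <- -A1 * p$Gm
  J[4L, 9L, ] <- -A1 * (p$k / p$mu) * 2 * c1
  J[5L, 6L, ] <- 1
  J[6L, 3L, ] <- -2 * p$Br * S[3L, ] / A1
  if (p$joule_variant == "velocity") {
    J[6L, 2L, ] <- -2 * p$Br * p$M^2 * (S[2L, ] + 1)
  } else {
    J[6L, 3L, ] <- J[6L, 3L, ] - 2 * p$Br * p$M^2 * (S[3L, ] + 1)
  }
  J[6L, 6L, ] <- -p$Pr * p$Nb * S[8L, ] - 2 * p$Nt * p$Pr * S[6L, ]
  J[6L, 8L, ] <- -p$Pr * p$Nb * S[6L, ]
  J[7L, 8L, ] <- 1
  if (p$Nb > 0) {
    r <- -(p$Nt / p$Nb)
    J[8L, , ] <- r * J[6L, , ]
  }
  J[9L, 10L, ] <- 1
  J[10L, 3L, ] <- c1
  J[10L, 9L, ] <- 2 * c1
  J
}

#' Right-hand side of the reduced first-order system
#'
#' Evaluates the derivative of the 10-component state
#' \eqn{(\psi, \psi', \psi'', \psi''', \theta, \theta', \Omega, \Omega', w, w')}
#' at one transverse point. The system is autonomous in \code{y}; the
#' argument is kept for the standard ODE signature.
#'
#' @param y transverse position (unused; the system is autonomous).
#' @param state numeric vector of length 10 (order as above).
#' @param params a \code{model_params} object.
#' @return Named numeric vector of the 10 derivatives.
#' @examples
#' s <- numeric(10); s[3] <- 1
#' ode_rhs(0, s, model_params(Gr = 0, Gm = 0))
#' @export
ode_rhs <- function(y, state, params) {
  validate_params(params)
  stopifnot(length(state) == 10L, all(is.finite(state)))
  d <- drop(rhs_mat(matrix(state, nrow = 10L), params))
  names(d) <- paste0("d_", STATE_NAMES)
  d
}

#' Boundary-condition residuals
#'
#' The ten two-point conditions of the flow: at the lower wall \code{h2}
#' \eqn{\psi = -q/2}, \eqn{\psi' = u_o}, \eqn{\theta, \Omega} at their lower
#' wall values, \eqn{w = 0}; at the upper wall \code{h1} \eqn{\psi = +q/2},
#' \eqn{\psi' = u_o}, \eqn{\theta, \Omega} at their upper wall values,
#' \eqn{w = 0}. Under the default orientation the lower wall is the heated
#' one (\eqn{\theta = \Omega = 1}).
#'
#' Residuals are attained value minus target, in the fixed order
#' \code{(psi, u, theta, omega, w)} at the lower wall followed by the same
#' five at the upper wall.
#'
#' @param s_lower,s_upper length-10 state vectors at \code{h2} and \code{h1}.
#' @param st a \code{\link{station}}.
#' @param params a \code{model_params} object.
#' @return Named numeric vector of 10 residuals; all zero iff the boundary
#'   conditions hold exactly.
#' @export
bc_residuals <- function(s_lower, s_upper, st, params) {
  stopifnot(length(s_lower) == 10L, length(s_upper) == 10L)
  wv <- bc_wall_values(params)
  r <- c(s_lower[1L] + params$q / 2,
         s_lower[2L] - st$uo,
         s_lower[5L] - wv$lower[1L],
         s_lower[7L] - wv$lower[2L],
         s_lower[9L],
         s_upper[1L] - params$q / 2,
         s_upper[2L] - st$uo,
         s_upper[5L] - wv$upper[1L],
         s_upper[7L] - wv$upper[2L],
         s_upper[9L])
  names(r) <- c(paste0(c("psi", "u", "theta", "omega", "w"), "_lower"),
                paste0(c("psi", "u", "theta", "omega", "w"), "_upper"))
  r
}

# Indices (into the 10-state) and targets of the five lower and five upper
# boundary conditions, shared by all three solvers.
bc_spec <- function(st, params) {
  wv <- bc_wall_values(params)
  list(idx = c(1L, 2L, 5L, 7L, 9L),
       lower = c(-params$q / 2, st$uo, wv$lower[1L], wv$lower[2L], 0),
       upper = c(params$q / 2, st$uo, wv$upper[1L], wv$upper[2L], 0))
}
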