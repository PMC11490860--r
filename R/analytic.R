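#' Closed-form solution in the decoupled linear limit
#'
#' With \code{Gr = Gm = k = 0} the momentum equation decouples from
#' temperature, concentration and microrotation and becomes linear:
#' \deqn{u'' - m^2 (u + 1) = (1+\lambda_1)\,dp/dx, \qquad
#'       m^2 = (1+\lambda_1)(M^2 + 1/Da),}
#' with \eqn{u = u_o} at both walls and the flux condition
#' \eqn{\int_{h_2}^{h_1} u\,dy = q} fixing the constant \eqn{dp/dx}.
#' Writing \eqn{v = u + 1}, the solution is
#' \eqn{v = A\cosh m(y-y_c) + B\sinh m(y-y_c) + D} about the channel centre
#' \eqn{y_c}; for \eqn{m (h_1-h_2) < 10^{-4}} the plane-Poiseuille
#' quadratic limit is used to avoid catastrophic cancellation (the neglected
#' term is \eqn{O(m^2)}).
#'
#' @param st a \code{\link{station}}.
#' @param params a \code{model_params} object with
#'   \code{Gr = Gm = k = 0} exactly (otherwise an error).
#' @return List with \code{u} (vectorised function of \code{y}),
#'   \code{dudy} (its derivative), \code{psi} (stream function with
#'   \code{psi(h2) = -q/2}), and the scalar \code{dpdx}.
#' @examples
#' p <- model_params(Gr = 0, Gm = 0, k = 0, M = 0, Da = 1e9, lambda1 = 0,
#'                   alpha = 0, a = 0, b = 0, d = 1)
#' sol <- analytic_limit_solution(station(0, p), p)
#' sol$u(0)      # 1.25 for q = 1: plane Poiseuille in the wave frame
#' sol$dpdx      # -4.5
#' @export
analytic_limit_solution <- function(st, params) {
  validate_params(params)
  if (params$Gr != 0 || params$Gm != 0 || params$k != 0)
    stop("analytic_limit_solution requires Gr = Gm = k = 0 exactly",
         call. = FALSE)
  A1 <- 1 + params$lambda1
  beta <- params$M^2 + 1 / params$Da
  m2 <- A1 * beta
  m <- sqrt(m2)
  h1 <- st$h1; h2 <- st$h2
  yc <- (h1 + h2) / 2
  H <- h1 - h2
  U <- st$uo + 1                    # v = u + 1 at both walls
  FF <- params$q + H                # integral of v

  if (m * H < 1e-4) {
    # quadratic limit: v = C/2 (y-yc)^2 + B (y-yc) + A, v'' = C
    # v(+-H/2) = U  =>  B = 0, A + C H^2/8 = U
    # int v = A H + C H^3 / 24 = FF
    # solve for A, C:
    Cc <- (FF - U * H) / (H^3 / 24 - H^3 / 8)
    Aa <- U - Cc * H^2 / 8
    dpdx <- Cc / A1
    u <- function(y) Aa + Cc * (y - yc)^2 / 2 - 1
    dudy <- function(y) Cc * (y - yc)
    psi <- function(y) {
      t <- y - yc; t2 <- h2 - yc
      (Aa - 1) * (t - t2) + Cc * (t^3 - t2^3) / 6 - params$q / 2
    }
  } else {
    t1 <- (h1 - yc); t2 <- (h2 - yc)      # = +-H/2
    Mm <- rbind(c(cosh(m * t1), sinh(m * t1), 1),
                c(cosh(m * t2), sinh(m * t2), 1),
                c((sinh(m * t1) - sinh(m * t2)) / m,
                  (cosh(m * t1) - cosh(m * t2)) / m, H))
    coef <- solve(Mm, c(U, U, FF))
    Aa <- coef[1L]; Bb <- coef[2L]; Dd <- coef[3L]
    dpdx <- -beta * Dd                    # = -m^2 D / (1+lambda1)
    u <- function(y) {
      t <- y - yc
      Aa * cosh(m * t) + Bb * sinh(m * t) + Dd - 1
    }
    dudy <- function(y) {
      t <- y - yc
      m * (Aa * sinh(m * t) + Bb * cosh(m * t))
    }
    psi <- function(y) {
      t <- y - yc; tl <- h2 - yc
      P <- function(s) (Aa * sinh(m * s) + Bb * cosh(m * s)) / m + (Dd - 1) * s
      P(t) - P(tl) - params$q / 2
    }
  }
  list(u = u, dudy = dudy, psi = psi, dpdx = dpdx)
}
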