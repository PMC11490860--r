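#' Model parameters for the ciliated-channel micropolar nanofluid problem
#'
#' Collects every dimensionless group of the reduced (lubrication-limit) model
#' together with the channel/cilia geometry constants, validates the
#' admissibility constraints, and carries the three model-variant flags.
#'
#' The defaults are the baseline conditions of the study this package
#' reproduces: \code{alpha = 0.2}, \code{M = 1}, \code{eps = delta = 0.1},
#' \code{a = 0.3}, \code{b = 0.5}, \code{phi = pi/3}, \code{Pr = 1},
#' \code{lambda1 = 0.2}, \code{Da = 0.5}, \code{Br = 1}, \code{Gr = Gm = 0.5},
#' \code{k = 1}, \code{Nt = 0.2}, \code{mu = 0.5}, \code{gamma1 = 0.5},
#' \code{d1 = 0.3}; where the source did not print a value we fix
#' \code{Nb = 0.5}, \code{d = 1} and \code{q = 1}.
#'
#' @param M Hartmann number (Lorentz drag / viscous force), >= 0.
#' @param Gr thermal Grashof number (thermal buoyancy / viscous force).
#' @param Gm nanoparticle Grashof number (solutal buoyancy / viscous force).
#' @param Da Darcy number (dimensionless permeability of the porous drag
#'   term \code{(u+1)/Da}), > 0.
#' @param Pr Prandtl number (momentum / thermal diffusivity), >= 0.
#' @param Br Brinkman number (viscous-dissipation heating / conduction), >= 0.
#' @param Nt thermophoresis parameter, >= 0.
#' @param Nb Brownian-motion parameter, > 0 (0 permitted only with
#'   \code{Nt = 0}).
#' @param lambda1 ratio of relaxation to retardation times; \code{1 + lambda1}
#'   must be positive.
#' @param k micropolar viscosity constant (couples microrotation into
#'   momentum through \code{k/mu}).
#' @param mu viscosity constant in the coupling \code{k/mu}, > 0.
#' @param gamma1 microrotation (spin-gradient) coefficient, > 0.
#' @param d1 microgyration length constant, > 0.
#' @param alpha cilia-length parameter.
#' @param eps cilia amplitude parameter.
#' @param delta wave number (channel half-width / metachronal wavelength).
#' @param a upper-wall wave amplitude, >= 0.
#' @param b lower-wall wave amplitude, >= 0.
#' @param d lower-wall mean half-width, > 0.
#' @param phi phase difference between the two wall waves, radians in
#'   \code{[0, pi]}.
#' @param q wave-frame volumetric flow rate between the walls; the stream
#'   function takes the values \code{-q/2} and \code{+q/2} at the lower and
#'   upper wall.
#' @param bc_orientation which wall is heated: \code{"lower_hot"} (default;
#'   temperature and concentration equal 1 at the lower wall \code{h2}, 0 at
#'   \code{h1}) or \code{"upper_hot"} (flipped).
#' @param uo_phase phase convention of the cilia slip velocity:
#'   \code{"wavelength"} (default, \code{cos(2*pi*x)}, phase-locked to the
#'   wall deformation) or \code{"literal"} (\code{cos(x)}).
#' @param joule_variant argument of the Joule-heating term:
#'   \code{"velocity"} (default, \code{M^2 (u+1)^2}) or \code{"shear"}
#'   (\code{M^2 (du/dy + 1)^2}).
#'
#' @return An object of class \code{"model_params"} (a validated named list).
#' @examples
#' p <- model_params()              # baseline
#' p2 <- model_params(M = 3, Gr = 2)
#' @export
model_params <- function(M = 1, Gr = 0.5, Gm = 0.5, Da = 0.5, Pr = 1,
                         Br = 1, Nt = 0.2, Nb = 0.5, lambda1 = 0.2,
                         k = 1, mu = 0.5, gamma1 = 0.5, d1 = 0.3,
                         alpha = 0.2, eps = 0.1, delta = 0.1,
                         a = 0.3, b = 0.5, d = 1, phi = pi / 3, q = 1,
                         bc_orientation = c("lower_hot", "upper_hot"),
                         uo_phase = c("wavelength", "literal"),
                         joule_variant = c("velocity", "shear")) {
  p <- list(M = M, Gr = Gr, Gm = Gm, Da = Da, Pr = Pr, Br = Br,
            Nt = Nt, Nb = Nb, lambda1 = lambda1, k = k, mu = mu,
            gamma1 = gamma1, d1 = d1, alpha = alpha, eps = eps,
            delta = delta, a = a, b = b, d = d, phi = phi, q = q,
            bc_orientation = match.arg(bc_orientation),
            uo_phase = match.arg(uo_phase),
            joule_variant = match.arg(joule_variant))
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks the admissibility invariants: positivity guards
#' (\code{Da > 0}, \code{Nb > 0} unless \code{Nt = 0}, \code{1 + lambda1 > 0},
#' \code{mu > 0}, \code{gamma1 > 0}, \code{d1 > 0}), ranges
#' (\code{M, Br, Nt, a, b >= 0}, \code{Pr >= 0}, \code{d > 0},
#' \code{0 <= phi <= pi}) and the wall non-contact relation
#' \code{a^2 + b^2 + 2 a b cos(phi) <= (1 + d)^2}.
#'
#' @param p a \code{model_params} object (or bare list with the same fields).
#' @return \code{p}, invisibly, if valid; otherwise an error describing the
#'   violated constraint.
#' @export
validate_params <- function(p) {
  num <- c("M", "Gr", "Gm", "Da", "Pr", "Br", "Nt", "Nb", "lambda1", "k",
           "mu", "gamma1", "d1", "alpha", "eps", "delta", "a", "b", "d",
           "phi", "q")
  for (f in num) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  if (p$Da <= 0) stop("Da must be > 0", call. = FALSE)
  if (p$Nb < 0 || (p$Nb == 0 && p$Nt != 0))
    stop("Nb must be > 0 (Nb = 0 is only admissible with Nt = 0)",
         call. = FALSE)
  if (1 + p$lambda1 <= 0) stop("1 + lambda1 must be > 0", call. = FALSE)
  if (p$mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (p$gamma1 <= 0) stop("gamma1 must be > 0", call. = FALSE)
  if (p$d1 <= 0) stop("d1 must be > 0", call. = FALSE)
  if (p$M < 0) stop("M must be >= 0", call. = FALSE)
  if (p$Pr < 0) stop("Pr must be >= 0", call. = FALSE)
  if (p$Br < 0) stop("Br must be >= 0", call. = FALSE)
  if (p$Nt < 0) stop("Nt must be >= 0", call. = FALSE)
  if (p$a < 0 || p$b < 0) stop("wave amplitudes a, b must be >= 0",
                               call. = FALSE)
  if (p$d <= 0) stop("mean lower half-width d must be > 0", call. = FALSE)
  if (p$phi < 0 || p$phi > pi) stop("phi must lie in [0, pi]", call. = FALSE)
  lhs <- p$a^2 + p$b^2 + 2 * p$a * p$b * cos(p$phi)
  if (lhs > (1 + p$d)^2)
    stop("amplitude admissibility violated: a^2 + b^2 + 2ab cos(phi) = ",
         signif(lhs, 6), " exceeds (1 + d)^2 = ", signif((1 + p$d)^2, 6),
         " (walls would touch)", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Micropolar nanofluid channel model parameters\n")
  num <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[num])
  cat(paste0("  ", format(names(vals), width = 8), " = ",
             format(vals, digits = 6)), sep = "\n")
  cat("  flags: bc_orientation=", x$bc_orientation,
      ", uo_phase=", x$uo_phase,
      ", joule_variant=", x$joule_variant, "\n", sep = "")
  invisible(x)
}

#' Wall positions of the ciliated asymmetric channel
#'
#' The channel envelope in the wave frame:
#' \deqn{h_1(x) = 1 + a\cos(2\pi x), \qquad
#'       h_2(x) = -d - b\cos(2\pi x + \phi),}
#' with \code{x} in wavelength units.
#'
#' @param x axial position (wavelength units); may be a vector.
#' @param params a \code{model_params} object.
#' @return A list with numeric components \code{h1} and \code{h2}
#'   (same length as \code{x}), with \code{h1 > h2} guaranteed for
#'   admissible parameters.
#' @examples
#' wall_positions(0, model_params())
#' @export
wall_positions <- function(x, params) {
  validate_params(params)
  h1 <- 1 + params$a * cos(2 * pi * x)
  h2 <- -params$d - params$b * cos(2 * pi * x + params$phi)
  list(h1 = h1, h2 = h2)
}

#' Cilia slip velocity at the walls
#'
#' The metachronal beating of the cilia tips imposes, in the wave frame, an
#' axial slip velocity at both walls that oscillates about \code{-1}:
#' \deqn{u_o(x) = -1 - 2\pi\alpha\epsilon\delta\cos(2\pi x)}
#' (default phase convention, locked to the wall deformation). With
#' \code{uo_phase = "literal"} the phase is \code{cos(x)}.
#'
#' @inheritParams wall_positions
#' @return Numeric vector of slip velocities, one per \code{x}.
#' @examples
#' cilia_velocity(0, model_params())   # -1 - 2*pi*0.002
#' @export
cilia_velocity <- function(x, params) {
  validate_params(params)
  phase <- if (params$uo_phase == "wavelength") 2 * pi * x else x
  -1 - 2 * pi * params$alpha * params$eps * params$delta * cos(phase)
}

#' Evaluate one axial station
#'
#' Bundles an axial position with the wall positions and cilia slip velocity
#' evaluated there; every solver call takes a station.
#'
#' @inheritParams wall_positions
#' @return An object of class \code{"station"}: list with \code{x},
#'   \code{h1}, \code{h2}, \code{uo}.
#' @examples
#' station(0, model_params())
#' @export
station <- function(x, params) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  w <- wall_positions(x, params)
  if (w$h1 <= w$h2)
    stop("degenerate station: h1 <= h2 at x = ", x, call. = FALSE)
  st <- list(x = x, h1 = w$h1, h2 = w$h2, uo = cilia_velocity(x, params))
  class(st) <- "station"
  st
}

#' @export
print.station <- function(x, ...) {
  cat(sprintf("Station x = %g: h1 = %.6g, h2 = %.6g, uo = %.8g\n",
              x$x, x$h1, x$h2, x$uo))
  invisible(x)
}

# Wall values of (theta, Omega) under the orientation flag:
# list(lower = c(theta, Omega), upper = c(theta, Omega)).
bc_wall_values <- function(params) {
  if (params$bc_orientation == "lower_hot")
    list(lower = c(1, 1), upper = c(0, 0))
  else
    list(lower = c(0, 0), upper = c(1, 1))
}
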