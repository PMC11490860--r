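# Built-in verification suite: the package's own acceptance-style property
# checks, runnable programmatically or through the CLI `verify` command.

#' Standard cross-validation panel
#'
#' Ten (parameters, station) cases spanning the studied ranges of the
#' transport groups (Hartmann, Darcy, Prandtl, Brinkman, the two Grashof
#' numbers, micropolar coupling, relaxation ratio), used for the
#' tri-solver cross-validation and invariant audits.
#'
#' @return A list of lists, each with elements \code{params} and \code{x}.
#' @export
panel_cases <- function() {
  list(
    list(params = model_params(),                      x = 0),
    list(params = model_params(M = 0),                 x = 0),
    list(params = model_params(M = 3),                 x = 0),
    list(params = model_params(Da = 0.2),              x = 0),
    list(params = model_params(Da = 0.8, lambda1 = 0.8), x = 0),
    list(params = model_params(Pr = 7, Nt = 0.8),      x = 0),
    list(params = model_params(Br = 4),                x = 0),
    list(params = model_params(Gr = 2, Gm = 2),        x = 0),
    list(params = model_params(k = 3),                 x = 0),
    list(params = model_params(),                      x = 0.25))
}

# decoupled flat-channel configuration of the plane-Poiseuille check
poiseuille_params <- function() {
  model_params(Gr = 0, Gm = 0, k = 0, M = 0, Da = 1e9, lambda1 = 0,
               alpha = 0, a = 0, b = 0, d = 1, q = 1)
}

#' Run the verification suite
#'
#' Recomputes the package's property checks from scratch: closed-form
#' equivalence in the decoupled linear limit, exact first integral of the
#' concentration equation, pressure-gradient constancy, tri-solver
#' cross-validation, conservation/boundary audits, finite-difference
#' convergence order, symmetry, and the orientation-robust qualitative
#' trends.
#'
#' @param checks which checks to run (default all).
#' @param opts solver options.
#' @return A \code{data.frame} with columns \code{check, measure, threshold,
#'   pass}; attribute \code{"details"} carries per-check values.
#' @export
run_verification <- function(checks = c("poiseuille", "linear_limit",
                                        "first_integral", "pressure",
                                        "tri_solver", "conservation",
                                        "fd_order", "symmetry", "trends"),
                             opts = solver_options()) {
  checks <- match.arg(checks, several.ok = TRUE)
  rows <- list()
  details <- list()
  push <- function(check, measure, threshold) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, measure = measure, threshold = threshold,
      pass = is.finite(measure) && measure <= threshold)
  }

  if ("poiseuille" %in% checks) {
    p <- poiseuille_params()
    st <- station(0, p)
    ana <- analytic_limit_solution(st, p)
    sol <- solve_station(st, p, opts)
    uc <- center_values(sol)[["u"]]
    pg <- pressure_gradient(sol, p)
    err <- max(abs(uc - ana$u(0)), abs(pg$dpdx_mean - ana$dpdx))
    details$poiseuille <- list(u_center = uc, dpdx = pg$dpdx_mean,
                               u_exact = ana$u(0), dpdx_exact = ana$dpdx)
    push("poiseuille", err, 1e-6)
  }

  if ("linear_limit" %in% checks) {
    err <- 0
    for (M in c(1, 2)) for (Da in c(0.2, 0.8)) for (l1 in c(0, 0.2)) {
      p <- model_params(Gr = 0, Gm = 0, k = 0, M = M, Da = Da,
                        lambda1 = l1)
      st <- station(0, p)
      ana <- analytic_limit_solution(st, p)
      sol <- solve_station(st, p, opts)
      err <- max(err, max(abs(sol$states[, "u"] - ana$u(sol$y_grid))))
    }
    details$linear_limit <- list(max_err = err)
    push("linear_limit", err, 1e-6)
  }

  if ("first_integral" %in% checks) {
    p <- model_params()
    sol <- solve_station(station(0, p), p, opts)
    a <- invariant_audit(sol, p)
    details$first_integral <- a
    push("first_integral", a$first_integral_dev, 1e-6)
  }

  if ("pressure" %in% checks || "conservation" %in% checks ||
      "tri_solver" %in% checks) {
    panel <- panel_cases()
    pmax_rel <- 0; cons <- 0; bcmax <- 0; tri <- 0
    for (cs in panel) {
      st <- station(cs$x, cs$params)
      sol <- robust_solve(st, cs$params, opts)
      pg <- pressure_gradient(sol, cs$params)
      pmax_rel <- max(pmax_rel, pg$dpdx_dev / max(1, abs(pg$dpdx_mean)))
      a <- invariant_audit(sol, cs$params)
      cons <- max(cons, a$flux_quad_err)
      bcmax <- max(bcmax, a$max_bc_residual)
      if ("tri_solver" %in% checks) {
        sh <- shooting_solve(st, cs$params,
                             solver_options(method = "shooting"),
                             init = sol)
        fdo <- fd_solve(st, cs$params,
                        solver_options(method = "finite_difference",
                                       initial_mesh_n = 401L))
        yref <- seq(st$h2, st$h1, length.out = 201L)
        Sc <- interpolate_solution(sol, yref)
        Ss <- interpolate_solution(sh, yref)
        Sf <- interpolate_solution(fdo, yref)
        tri <- max(tri, max(abs(Sc - Ss)), max(abs(Sc - Sf)),
                   max(abs(Ss - Sf)))
      }
    }
    if ("pressure" %in% checks) {
      details$pressure <- list(max_rel_dev = pmax_rel)
      push("pressure", pmax_rel, 1e-5)
    }
    if ("conservation" %in% checks) {
      details$conservation <- list(max_flux_err = cons,
                                   max_bc_residual = bcmax)
      push("conservation_flux", cons, 1e-6)
      push("conservation_bc", bcmax, 1e-8)
    }
    if ("tri_solver" %in% checks) {
      details$tri_solver <- list(max_dist = tri)
      push("tri_solver", tri, 1e-4)
    }
  }

  if ("fd_order" %in% checks) {
    p <- model_params(Gr = 0, Gm = 0, k = 0, M = 2, Da = 0.5,
                      lambda1 = 0.2)
    st <- station(0, p)
    ana <- analytic_limit_solution(st, p)
    errs <- vapply(c(201L, 401L, 801L), function(n) {
      s <- fd_solve(st, p, solver_options(method = "finite_difference",
                                          initial_mesh_n = n))
      max(abs(s$states[, "u"] - ana$u(s$y_grid)))
    }, numeric(1L))
    ords <- log2(errs[-3L] / errs[-1L])
    details$fd_order <- list(errors = errs, orders = ords)
    push("fd_order", -min(ords), -1.9)   # pass iff min order >= 1.9
  }

  if ("symmetry" %in% checks) {
    p <- model_params(Gr = 0, Gm = 0, k = 0, b = 0.3, a = 0.3, d = 1,
                      phi = 0)
    st <- station(0, p)
    sol <- solve_station(st, p, opts)
    yy <- seq(st$h2, st$h1, length.out = 201L)
    u1 <- interpolate_solution(sol, yy)[, "u"]
    u2 <- interpolate_solution(sol, -yy)[, "u"]
    details$symmetry <- list(max_asym = max(abs(u1 - u2)))
    push("symmetry", max(abs(u1 - u2)), 1e-6)
  }

  if ("trends" %in% checks) {
    sp <- sweep_spec(model_params(),
                     vary = list(M = c(0, 1, 2, 3),
                                 Pr = c(0.015, 1, 7, 21)),
                     stations = 0)
    sw <- run_sweep(sp, opts)
    tr <- trend_report(sw)
    hard <- tr[!is.na(tr$assert) & tr$assert, , drop = FALSE]
    nfail <- sum(!hard$matches)
    details$trends <- tr
    push("trends", nfail, 0)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}
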