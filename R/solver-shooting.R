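# Shooting solver: five conditions are known at the lower wall
# (psi = -q/2, psi' = uo, theta, Omega at their wall values, w = 0);
# damped Newton on the five unknown lower-wall derivatives
# (psi'', psi''', theta', Omega', w') drives the five upper-wall residuals
# to zero. Integration uses a high-order Runge-Kutta (Dormand-Prince 4(5))
# initial-value integrator at tight tolerance. The Newton Jacobian is
# formed by finite differences; all six required trajectories (base plus
# five perturbations) are integrated together as one augmented system so
# each Newton iteration costs two integrator calls. A cold start ramps the
# transport couplings (M, Br, Gr, Gm, Pr, Nt) by adaptive continuation
# from the fully decoupled linear problem; warm starts (e.g. from a
# collocation solution in cross-validation) skip the ramp.

shoot_lower_state <- function(z, st, params) {
  bs <- bc_spec(st, params)
  s <- numeric(10L)
  s[bs$idx] <- bs$lower
  s[c(3L, 4L, 6L, 8L, 10L)] <- z
  s
}

# integrate m trajectories at once; Z is 5 x m; returns 10 x m final states
# (or the full mesh output when `times` has more than two entries)
shoot_integrate <- function(Z, st, params, times, full = FALSE) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  Y0 <- vapply(seq_len(m), function(j) shoot_lower_state(Z[, j], st, params),
               numeric(10L))
  fn <- function(t, y, parms)
    list(as.numeric(rhs_mat(matrix(y, nrow = 10L), params)))
  out <- suppressWarnings(
    deSolve::ode(y = as.numeric(Y0), times = times, func = fn,
                 parms = NULL, method = "ode45",
                 rtol = 1e-10, atol = 1e-11, maxsteps = 3000))
  if (nrow(out) < length(times) || any(!is.finite(out[, -1L])))
    stop("integration failed", call. = FALSE)
  if (full) out[, -1L, drop = FALSE]
  else matrix(out[nrow(out), -1L], nrow = 10L)
}

shoot_res_of <- function(Send, st, params) {
  bs <- bc_spec(st, params)
  Send[bs$idx, , drop = FALSE] - bs$upper
}

shoot_newton <- function(z, st, params, ntol, maxit = 40L) {
  ends <- c(st$h2, st$h1)
  r <- tryCatch(
    drop(shoot_res_of(shoot_integrate(z, st, params, ends), st, params)),
    error = function(e) rep(Inf, 5L))
  rn <- max(abs(r))
  history <- rn
  iter <- 0L
  for (it in 1:maxit) {
    if (rn < ntol) break
    iter <- it
    dz <- 1e-7 * pmax(1, abs(z))
    Zp <- matrix(z, 5L, 5L) + diag(dz)
    Rp <- tryCatch(
      shoot_res_of(shoot_integrate(Zp, st, params, ends), st, params),
      error = function(e) NULL)
    if (is.null(Rp)) break
    Jm <- (Rp - r) / rep(dz, each = 5L)
    step <- tryCatch(solve(Jm, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (half in 0:12) {
      znew <- z + lam * step
      rnew <- tryCatch(
        drop(shoot_res_of(shoot_integrate(znew, st, params, ends),
                          st, params)),
        error = function(e) NULL)
      if (!is.null(rnew) && all(is.finite(rnew))) {
        rn_new <- max(abs(rnew))
        if (rn_new < (1 - 0.25 * lam) * rn + ntol) {
          z <- znew; r <- rnew; rn <- rn_new
          improved <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    history <- c(history, rn)
    if (!improved) break
  }
  list(z = z, rn = rn, iter = iter, history = history)
}

shooting_solve <- function(st, params,
                           opts = solver_options(method = "shooting"),
                           init = NULL) {
  validate_params(params)
  n_out <- max(opts$initial_mesh_n, 201L)
  times <- seq(st$h2, st$h1, length.out = n_out)
  ntol <- min(1e-10, opts$tolerance)
  history <- numeric(0)
  ramp_names <- c("M", "Br", "Gr", "Gm", "Pr", "Nt")
  params_at <- function(s) {
    p_s <- params
    for (nm in ramp_names) p_s[[nm]] <- s * params[[nm]]
    p_s
  }
  nt <- NULL
  if (!is.null(init)) {
    z <- init$states[1L, c(3L, 4L, 6L, 8L, 10L)]
    nt <- shoot_newton(z, st, params, ntol, maxit = 12L)
    history <- nt$history
  }
  if (is.null(nt) || nt$rn >= ntol) {
    # adaptive continuation from the fully decoupled linear problem (s = 0)
    z <- initial_guess(st, params, 11L)$states[1L, c(3L, 4L, 6L, 8L, 10L)]
    s_cur <- 0; ds <- 1; stages <- 0L
    nt <- shoot_newton(z, st, params_at(0), ntol, maxit = 12L)
    history <- c(history, nt$history)
    if (nt$rn < ntol) z <- nt$z
    while (nt$rn < ntol && s_cur < 1) {
      stages <- stages + 1L
      if (stages > 40L) { nt$rn <- Inf; break }
      s_try <- min(1, s_cur + ds)
      nt_try <- shoot_newton(z, st, params_at(s_try), ntol, maxit = 12L)
      history <- c(history, nt_try$history)
      if (nt_try$rn < ntol) {
        s_cur <- s_try; z <- nt_try$z; nt <- nt_try
        ds <- min(1, ds * 2)
      } else {
        ds <- ds / 2
        if (ds < 1 / 64) { nt <- nt_try; break }
      }
    }
    if (s_cur < 1) nt$rn <- Inf
  }
  if (is.null(nt) || !(nt$rn < max(ntol, opts$tolerance))) {
    cond <- structure(
      class = c("ciliaflow_convergence_error", "error", "condition"),
      list(message = sprintf(
        "shooting Newton stalled at residual %.3g",
        if (is.null(nt)) Inf else nt$rn),
        call = NULL, last = NULL, history = history))
    stop(cond)
  }
  S <- unname(shoot_integrate(nt$z, st, params, times, full = TRUE))
  new_solution_field(st, params, times, S, TRUE, nt$rn, "shooting",
                     length(history))
}
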