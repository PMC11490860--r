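# Second-order finite-difference solver on a uniform grid, acting on the
# high-order form of the model: the fourth-order stream-function equation
# plus the three second-order equations for temperature, concentration and
# microrotation, with the pressure gradient eliminated (the fourth-order
# psi formulation). Damped Newton on the assembled nonlinear system with a
# sparse analytic Jacobian. Serves as an independent oracle for the
# collocation solver; observed convergence order is 2.

# Fornberg (1988) finite-difference weights: derivatives 0..m at point z
# from nodes x. Returns a length(x) x (m+1) matrix.
fdweights <- function(z, x, m) {
  nx <- length(x)
  C <- matrix(0, nx, m + 1L)
  c1 <- 1; c4 <- x[1L] - z
  C[1L, 1L] <- 1
  for (i in 2:nx) {
    mn <- min(i, m + 1L)
    c2 <- 1; c5 <- c4; c4 <- x[i] - z
    for (j in 1:(i - 1L)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1L) {
        if (mn >= 2L)
          for (k in seq(mn, 2L))
            C[i, k] <- c1 * ((k - 1) * C[i - 1L, k - 1L] -
                               c5 * C[i - 1L, k]) / c2
        C[i, 1L] <- -c1 * c5 * C[i - 1L, 1L] / c2
      }
      if (mn >= 2L)
        for (k in seq(mn, 2L))
          C[j, k] <- (c4 * C[j, k] - (k - 1) * C[j, k - 1L]) / c3
      C[j, 1L] <- c4 * C[j, 1L] / c3
    }
    c1 <- c2
  }
  C
}

fd_consts <- function(params) {
  list(A1 = 1 + params$lambda1,
       beta = params$M^2 + 1 / params$Da,
       c1 = params$k * params$d1 / params$gamma1,
       cw = params$k / params$mu)
}

# residual of the discrete system; x = c(psi, theta, omega, w), each length n
fd_residual <- function(x, st, params, n, h) {
  cc <- fd_consts(params)
  p <- params
  psi <- x[1:n]; th <- x[n + 1:n]; om <- x[2L * n + 1:n]; w <- x[3L * n + 1:n]
  bs <- bc_spec(st, params)
  it <- 2:(n - 1L)                      # second-order interior
  ip <- 3:(n - 2L)                      # fourth-order interior
  d2 <- function(f) (f[it + 1L] - 2 * f[it] + f[it - 1L]) / h^2
  d1 <- function(f) (f[it + 1L] - f[it - 1L]) / (2 * h)
  psipp <- d2(psi); u <- d1(psi); thp <- d1(th); omp <- d1(om)
  # psi rows
  d4 <- (psi[ip - 2L] - 4 * psi[ip - 1L] + 6 * psi[ip] -
           4 * psi[ip + 1L] + psi[ip + 2L]) / h^4
  j <- ip - 1L                          # index into interior vectors
  rpsi_int <- d4 - cc$A1 * (-p$Gr * thp[j] - p$Gm * omp[j] +
                              (cc$beta - cc$cw * cc$c1) * psipp[j] -
                              2 * cc$cw * cc$c1 * w[ip])
  rpsi <- c(psi[1L] + p$q / 2,
            (-3 * psi[1L] + 4 * psi[2L] - psi[3L]) / (2 * h) - st$uo,
            rpsi_int,
            (3 * psi[n] - 4 * psi[n - 1L] + psi[n - 2L]) / (2 * h) - st$uo,
            psi[n] - p$q / 2)
  # theta rows
  up <- if (p$joule_variant == "velocity") u + 1 else psipp + 1
  rth_int <- d2(th) + p$Br * (psipp^2 / cc$A1 + p$M^2 * up^2) +
    p$Pr * p$Nb * omp * thp + p$Nt * p$Pr * thp^2
  rth <- c(th[1L] - bs$lower[3L], rth_int, th[n] - bs$upper[3L])
  # omega rows (exactly linear: Omega'' + (Nt/Nb) theta'' = 0)
  rat <- if (p$Nb > 0) p$Nt / p$Nb else 0
  rom <- c(om[1L] - bs$lower[4L], d2(om) + rat * d2(th),
           om[n] - bs$upper[4L])
  # w rows
  rw <- c(w[1L], d2(w) - cc$c1 * (2 * w[it] + psipp), w[n])
  c(rpsi, rth, rom, rw)
}

# analytic sparse Jacobian
fd_jacobian <- function(x, st, params, n, h) {
  cc <- fd_consts(params)
  p <- params
  psi <- x[1:n]; th <- x[n + 1:n]; om <- x[2L * n + 1:n]
  it <- 2:(n - 1L); ip <- 3:(n - 2L)
  d2 <- function(f) (f[it + 1L] - 2 * f[it] + f[it - 1L]) / h^2
  d1 <- function(f) (f[it + 1L] - f[it - 1L]) / (2 * h)
  psipp <- d2(psi); u <- d1(psi); thp <- d1(th); omp <- d1(om)
  iP <- function(i) i; iT <- function(i) n + i
  iO <- function(i) 2L * n + i; iW <- function(i) 3L * n + i
  II <- list(); JJ <- list(); XX <- list()
  add <- function(i, j, v) {
    k <- length(II) + 1L
    II[[k]] <<- i; JJ[[k]] <<- j; XX[[k]] <<- v
  }
  # --- psi rows ---
  add(1L, 1L, 1)
  add(rep(2L, 3L), 1:3, c(-3, 4, -1) / (2 * h))
  np <- length(ip)
  for (s in -2:2) {
    coef <- c(1, -4, 6, -4, 1)[s + 3L] / h^4
    if (abs(s) <= 1L)
      coef <- coef - cc$A1 * (cc$beta - cc$cw * cc$c1) *
        c(1, -2, 1)[s + 2L] / h^2
    add(ip, ip + s, rep(coef, np))
  }
  add(ip, iT(ip + 1L), rep(cc$A1 * p$Gr / (2 * h), np))
  add(ip, iT(ip - 1L), rep(-cc$A1 * p$Gr / (2 * h), np))
  add(ip, iO(ip + 1L), rep(cc$A1 * p$Gm / (2 * h), np))
  add(ip, iO(ip - 1L), rep(-cc$A1 * p$Gm / (2 * h), np))
  add(ip, iW(ip), rep(cc$A1 * 2 * cc$cw * cc$c1, np))
  add(rep(n - 1L, 3L), (n - 2L):n, c(1, -4, 3) / (2 * h))
  add(n, n, 1)
  # --- theta rows ---
  add(iT(1L), iT(1L), 1)
  rth <- iT(it)
  cth <- p$Pr * p$Nb * omp + 2 * p$Nt * p$Pr * thp
  add(rth, iT(it + 1L), 1 / h^2 + cth / (2 * h))
  add(rth, iT(it), rep(-2 / h^2, n - 2L))
  add(rth, iT(it - 1L), 1 / h^2 - cth / (2 * h))
  add(rth, iO(it + 1L), p$Pr * p$Nb * thp / (2 * h))
  add(rth, iO(it - 1L), -p$Pr * p$Nb * thp / (2 * h))
  if (p$joule_variant == "velocity") {
    cpp <- 2 * p$Br * psipp / cc$A1
    cu <- 2 * p$Br * p$M^2 * (u + 1)
    add(rth, it + 1L, cpp / h^2 + cu / (2 * h))
    add(rth, it, -2 * cpp / h^2)
    add(rth, it - 1L, cpp / h^2 - cu / (2 * h))
  } else {
    cpp <- 2 * p$Br * psipp / cc$A1 + 2 * p$Br * p$M^2 * (psipp + 1)
    add(rth, it + 1L, cpp / h^2)
    add(rth, it, -2 * cpp / h^2)
    add(rth, it - 1L, cpp / h^2)
  }
  add(iT(n), iT(n), 1)
  # --- omega rows ---
  rat <- if (p$Nb > 0) p$Nt / p$Nb else 0
  add(iO(1L), iO(1L), 1)
  rom <- iO(it)
  for (s in c(-1L, 0L, 1L)) {
    coef <- c(1, -2, 1)[s + 2L] / h^2
    add(rom, iO(it + s), rep(coef, n - 2L))
    add(rom, iT(it + s), rep(rat * coef, n - 2L))
  }
  add(iO(n), iO(n), 1)
  # --- w rows ---
  add(iW(1L), iW(1L), 1)
  rw <- iW(it)
  add(rw, iW(it + 1L), rep(1 / h^2, n - 2L))
  add(rw, iW(it), rep(-2 / h^2 - 2 * cc$c1, n - 2L))
  add(rw, iW(it - 1L), rep(1 / h^2, n - 2L))
  for (s in c(-1L, 0L, 1L))
    add(rw, it + s, rep(-cc$c1 * c(1, -2, 1)[s + 2L] / h^2, n - 2L))
  add(iW(n), iW(n), 1)
  Matrix::sparseMatrix(i = unlist(II), j = unlist(JJ), x = unlist(XX),
                       dims = c(4L * n, 4L * n))
}

# scale factors bringing each residual row to O(1) units (roundoff-aware)
fd_row_scale <- function(n, h) {
  sp <- c(1, h, rep(h^3, n - 4L), h, 1)
  s2 <- c(1, rep(h^2, n - 2L), 1)
  c(sp, s2, s2, s2)
}

fd_solve <- function(st, params,
                     opts = solver_options(method = "finite_difference",
                                           initial_mesh_n = 401L),
                     init = NULL) {
  validate_params(params)
  n <- max(opts$initial_mesh_n, 101L)
  h <- (st$h1 - st$h2) / (n - 1L)
  y <- seq(st$h2, st$h1, length.out = n)
  if (is.null(init)) {
    g <- guess_states(st, params, y)
    x <- c(g$states[, 1L], g$states[, 5L], g$states[, 7L], g$states[, 9L])
  } else {
    S <- interpolate_solution(init, y)
    x <- c(S[, 1L], S[, 5L], S[, 7L], S[, 9L])
  }
  sc <- fd_row_scale(n, h)
  res <- fd_residual(x, st, params, n, h)
  rn <- max(abs(res * sc))
  history <- rn
  ok <- rn < 1e-9
  for (itn in 1:40) {
    if (ok) break
    J <- fd_jacobian(x, st, params, n, h)
    step <- tryCatch(as.numeric(Matrix::solve(J, -res)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    improved <- FALSE
    for (half in 0:50) {
      xn <- x + lam * step
      rnew <- fd_residual(xn, st, params, n, h)
      rn_new <- max(abs(rnew * sc))
      if (is.finite(rn_new) && rn_new < (1 - 0.25 * lam) * rn + 1e-12) {
        x <- xn; res <- rnew; rn <- rn_new
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    history <- c(history, rn)
    ok <- rn < 1e-9
    if (!improved) break
  }
  if (!ok) {
    cond <- structure(
      class = c("ciliaflow_convergence_error", "error", "condition"),
      list(message = sprintf(
        "finite-difference Newton stalled at scaled residual %.3g", rn),
        call = NULL, last = NULL, history = history))
    stop(cond)
  }
  S <- fd_recover_states(x, st, params, n, h, y)
  new_solution_field(st, params, y, S, TRUE, rn, "finite_difference",
                     length(history) - 1L)
}

# Recover the 10 state components from the primary fields. Boundary first
# derivatives of psi use exactly the stencil enforced by the boundary rows,
# so boundary-condition residuals of the recovered field vanish to roundoff;
# all other derivatives are second-order finite differences.
fd_recover_states <- function(x, st, params, n, h, y) {
  psi <- x[1:n]; th <- x[n + 1:n]; om <- x[2L * n + 1:n]; w <- x[3L * n + 1:n]
  der <- function(f, ord, npts) {
    out <- numeric(n)
    half <- (npts - 1L) %/% 2L
    for (i in 1:n) {
      j0 <- min(max(i - half, 1L), n - npts + 1L)
      idx <- j0:(j0 + npts - 1L)
      wgt <- fdweights(y[i], y[idx], ord)[, ord + 1L]
      out[i] <- sum(wgt * f[idx])
    }
    out
  }
  d1p <- der(psi, 1L, 5L)
  d1p[1L] <- (-3 * psi[1L] + 4 * psi[2L] - psi[3L]) / (2 * h)
  d1p[n] <- (3 * psi[n] - 4 * psi[n - 1L] + psi[n - 2L]) / (2 * h)
  S <- cbind(psi, d1p, der(psi, 2L, 5L), der(psi, 3L, 7L),
             th, der(th, 1L, 5L), om, der(om, 1L, 5L), w, der(w, 1L, 5L))
  colnames(S) <- STATE_NAMES
  S
}
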