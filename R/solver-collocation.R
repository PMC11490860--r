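# Adaptive fourth-order collocation (the classical 3-stage Lobatto IIIA /
# MIRK4 discretisation) for the 10-state two-point problem.
#
# Per mesh interval [y_i, y_{i+1}] with width h and node states Y_i:
#   Ymid = (Y_i + Y_{i+1})/2 - (h/8) (F_{i+1} - F_i)
#   R_i  = Y_{i+1} - Y_i - (h/6) (F_i + 4 F(Ymid) + F_{i+1})
# plus the ten boundary rows. The nonlinear system is solved by damped
# Newton with an analytic block-bidiagonal Jacobian, assembled sparse.
# The ODE residual of the quintic Hermite continuous extension, sampled at
# the 1/4 and 3/4 points of every interval, drives mesh refinement.

# Hermite quintic weights on [0,1] with data (value, derivative) at
# t = 0, 1/2, 1. Rows: sampled t; returns value and derivative weight
# matrices (length-6 rows against data ordering y0, f0, ym, fm, y1, f1
# with derivatives pre-scaled by h).
.hermite5_weights <- function(ts) {
  nodes <- c(0, 0, 0.5, 0.5, 1, 1)
  M <- matrix(0, 6L, 6L)
  pow <- 0:5
  for (r in seq(1L, 5L, by = 2L)) {
    tt <- nodes[r]
    M[r, ] <- tt^pow
    M[r + 1L, ] <- c(0, pow[-1L] * tt^(pow[-1L] - 1L))
  }
  Minv <- solve(M)
  wv <- t(vapply(ts, function(tt) as.numeric(tt^pow %*% Minv), numeric(6L)))
  wd <- t(vapply(ts, function(tt)
    as.numeric(c(0, pow[-1L] * tt^(pow[-1L] - 1L)) %*% Minv), numeric(6L)))
  # data ordering produced by M rows is (y0, f0, ym, fm, y1, f1) already
  list(val = wv, der = wd)
}
.H5W <- .hermite5_weights(c(0.25, 0.75))

colloc_system <- function(Y, st, params, y) {
  n <- ncol(Y)
  h <- diff(y)
  FF <- rhs_mat(Y, params)
  Yl <- Y[, -n, drop = FALSE]; Yr <- Y[, -1L, drop = FALSE]
  Fl <- FF[, -n, drop = FALSE]; Fr <- FF[, -1L, drop = FALSE]
  hm <- rep(h, each = 10L)
  Ym <- (Yl + Yr) / 2 - (Fr - Fl) * hm / 8
  Fm <- rhs_mat(Ym, params)
  R <- Yr - Yl - (Fl + 4 * Fm + Fr) * hm / 6
  g <- bc_residuals(Y[, 1L], Y[, n], st, params)
  list(R = R, g = g, FF = FF, Ym = Ym, Fm = Fm, h = h)
}

colloc_jacobian <- function(Y, sys, params) {
  n <- ncol(Y)
  N <- n - 1L
  J <- rhs_jac(Y, params)
  Jm <- rhs_jac(sys$Ym, params)
  I10 <- diag(10L)
  nz_per_block <- 100L
  ii <- integer(2L * N * nz_per_block + 10L)
  jj <- integer(length(ii))
  xx <- numeric(length(ii))
  pos <- 0L
  rowblock <- function(i) (i - 1L) * 10L
  for (i in seq_len(N)) {
    h <- sys$h[i]
    Jl <- J[, , i]; Jr <- J[, , i + 1L]; Jmi <- Jm[, , i]
    A <- -I10 - (h / 6) * Jl - (h / 3) * Jmi - (h^2 / 12) * (Jmi %*% Jl)
    B <- I10 - (h / 6) * Jr - (h / 3) * Jmi + (h^2 / 12) * (Jmi %*% Jr)
    rb <- rowblock(i)
    idx <- pos + seq_len(nz_per_block)
    ii[idx] <- rb + rep(1:10, times = 10L)
    jj[idx] <- rb + rep(1:10, each = 10L)
    xx[idx] <- as.numeric(A)
    pos <- pos + nz_per_block
    idx <- pos + seq_len(nz_per_block)
    ii[idx] <- rb + rep(1:10, times = 10L)
    jj[idx] <- rb + 10L + rep(1:10, each = 10L)
    xx[idx] <- as.numeric(B)
    pos <- pos + nz_per_block
  }
  # boundary rows: residual order (psi,u,theta,omega,w)_lower then _upper
  bidx <- c(1L, 2L, 5L, 7L, 9L)
  idx <- pos + 1:5
  ii[idx] <- 10L * N + 1:5
  jj[idx] <- bidx
  xx[idx] <- 1
  pos <- pos + 5L
  idx <- pos + 1:5
  ii[idx] <- 10L * N + 6:10
  jj[idx] <- 10L * N + bidx
  xx[idx] <- 1
  pos <- pos + 5L
  Matrix::sparseMatrix(i = ii[1:pos], j = jj[1:pos], x = xx[1:pos],
                       dims = c(10L * n, 10L * n))
}

colloc_newton <- function(Y, st, params, y, maxit = 40L, ntol = 1e-11) {
  sys <- colloc_system(Y, st, params, y)
  res <- c(as.numeric(sys$R), sys$g)
  rn <- max(abs(res))
  for (it in seq_len(maxit)) {
    if (rn < ntol) break
    Jac <- colloc_jacobian(Y, sys, params)
    step <- tryCatch(
      as.numeric(Matrix::solve(Jac, -res)),
      error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(Y = Y, sys = sys, rn = rn, ok = FALSE, iter = it))
    lam <- 1
    improved <- FALSE
    for (half in 0:50) {
      Ynew <- Y + matrix(lam * step, nrow = 10L)
      sys_new <- tryCatch(colloc_system(Ynew, st, params, y),
                          error = function(e) NULL)
      if (!is.null(sys_new)) {
        res_new <- c(as.numeric(sys_new$R), sys_new$g)
        rn_new <- max(abs(res_new))
        if (is.finite(rn_new) && rn_new < (1 - 0.25 * lam) * rn + ntol) {
          Y <- Ynew; sys <- sys_new; res <- res_new; rn <- rn_new
          improved <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved)
      return(list(Y = Y, sys = sys, rn = rn, ok = rn < ntol, iter = it))
  }
  list(Y = Y, sys = sys, rn = rn, ok = rn < ntol, iter = it)
}

# Scaled ODE residual of the quintic Hermite continuous extension,
# sampled at the 1/4 and 3/4 points of each interval; returns one
# estimate per interval.
colloc_error_estimate <- function(Y, sys, params) {
  n <- ncol(Y)
  N <- n - 1L
  h <- sys$h
  hm <- rep(h, each = 10L)
  dat <- list(Y[, -n, drop = FALSE], sys$FF[, -n, drop = FALSE] * hm,
              sys$Ym, sys$Fm * hm,
              Y[, -1L, drop = FALSE], sys$FF[, -1L, drop = FALSE] * hm)
  est <- numeric(N)
  for (s in 1:2) {
    Sv <- 0; Sd <- 0
    for (j in 1:6) {
      Sv <- Sv + .H5W$val[s, j] * dat[[j]]
      Sd <- Sd + .H5W$der[s, j] * dat[[j]]
    }
    f <- rhs_mat(Sv, params)
    r <- abs(Sd / hm - f) / (1 + abs(f))
    est <- pmax(est, apply(r, 2L, max))
  }
  est
}

# Evaluate the quintic continuous extension at interior points of given
# intervals (fractions in (0,1)); used when an interval is split in three.
colloc_eval_interior <- function(Y, sys, iv, frac) {
  W <- .hermite5_weights(frac)
  n <- ncol(Y)
  hm <- rep(sys$h, each = 10L)
  Fl <- sys$FF[, -n, drop = FALSE] * hm
  Fr <- sys$FF[, -1L, drop = FALSE] * hm
  Fm <- sys$Fm * hm
  dat <- list(Y[, -n, drop = FALSE], Fl, sys$Ym, Fm,
              Y[, -1L, drop = FALSE], Fr)
  out <- vector("list", length(frac))
  for (s in seq_along(frac)) {
    Sv <- 0
    for (j in 1:6) Sv <- Sv + W$val[s, j] * dat[[j]]
    out[[s]] <- Sv[, iv, drop = FALSE]
  }
  out
}

colloc_solve <- function(st, params, opts, init = NULL) {
  if (is.null(init)) init <- initial_guess(st, params, opts$initial_mesh_n)
  y <- init$y_grid
  Y <- t(init$states)
  history <- numeric(0)
  for (pass in 1:14) {
    nt <- colloc_newton(Y, st, params, y)
    history <- c(history, nt$rn)
    if (!nt$ok) {
      cond <- structure(
        class = c("ciliaflow_convergence_error", "error", "condition"),
        list(message = sprintf(
          "collocation Newton stalled at discrete residual %.3g (mesh %d)",
          nt$rn, length(y)),
          call = NULL,
          last = new_solution_field(st, params, y, t(nt$Y), FALSE, nt$rn,
                                    "collocation", nt$iter),
          history = history))
      stop(cond)
    }
    Y <- nt$Y
    est <- colloc_error_estimate(Y, nt$sys, params)
    rn <- max(max(est), max(abs(nt$sys$g)))
    if (rn <= opts$tolerance)
      return(new_solution_field(st, params, y, t(Y), TRUE, rn,
                                "collocation", nt$iter))
    bad <- which(est > opts$tolerance)
    triple <- est[bad] > 100 * opts$tolerance
    newn <- length(y) + length(bad) + sum(triple)
    if (newn > opts$max_mesh) {
      cond <- structure(
        class = c("ciliaflow_convergence_error", "error", "condition"),
        list(message = sprintf(
          "collocation mesh cap exceeded (%d > %d) at residual %.3g",
          newn, opts$max_mesh, rn),
          call = NULL,
          last = new_solution_field(st, params, y, t(Y), FALSE, rn,
                                    "collocation", nt$iter),
          history = history))
      stop(cond)
    }
    # refine: insert midpoint (have Ym already) or thirds
    ylist <- list(); Ylist <- list()
    split3 <- bad[triple]
    if (length(split3))
      thirds <- colloc_eval_interior(Y, nt$sys, split3, c(1 / 3, 2 / 3))
    k3 <- 0L
    for (i in seq_len(length(y) - 1L)) {
      ylist[[length(ylist) + 1L]] <- y[i]
      Ylist[[length(Ylist) + 1L]] <- Y[, i]
      if (i %in% split3) {
        k3 <- k3 + 1L
        ylist[[length(ylist) + 1L]] <- y[i] + (y[i + 1L] - y[i]) / 3
        Ylist[[length(Ylist) + 1L]] <- thirds[[1L]][, k3]
        ylist[[length(ylist) + 1L]] <- y[i] + 2 * (y[i + 1L] - y[i]) / 3
        Ylist[[length(Ylist) + 1L]] <- thirds[[2L]][, k3]
      } else if (i %in% bad) {
        ylist[[length(ylist) + 1L]] <- (y[i] + y[i + 1L]) / 2
        Ylist[[length(Ylist) + 1L]] <- nt$sys$Ym[, i]
      }
    }
    ylist[[length(ylist) + 1L]] <- y[length(y)]
    Ylist[[length(Ylist) + 1L]] <- Y[, length(y)]
    y <- unlist(ylist)
    Y <- do.call(cbind, Ylist)
  }
  cond <- structure(
    class = c("ciliaflow_convergence_error", "error", "condition"),
    list(message = "collocation failed to reach tolerance within refinement passes",
         call = NULL,
         last = new_solution_field(st, params, y, t(Y), FALSE,
                                   history[length(history)], "collocation"),
         history = history))
  stop(cond)
}

#' Solve the boundary-value problem at one station
#'
#' Solves the coupled stream-function/temperature/concentration/microrotation
#' two-point boundary-value problem on \code{[h2, h1]} with the method named
#' in \code{opts} (adaptive fourth-order collocation by default; damped-Newton
#' shooting and a second-order finite-difference solver are available as
#' independent cross-checks).
#'
#' @param st a \code{\link{station}}.
#' @param params a \code{model_params} object.
#' @param opts a \code{\link{solver_options}} object.
#' @param init optional \code{solution_field} used as warm start.
#' @return A converged \code{solution_field}. Non-convergence raises a
#'   condition of class \code{"ciliaflow_convergence_error"} carrying the
#'   last iterate (\code{$last}) and the residual history (\code{$history}).
#' @examples
#' p <- model_params()
#' sol <- solve_station(station(0, p), p, solver_options())
#' sol$converged
#' @export
solve_station <- function(st, params, opts = solver_options(), init = NULL) {
  validate_params(params)
  switch(opts$method,
         collocation = colloc_solve(st, params, opts, init),
         shooting = shooting_solve(st, params, opts, init),
         finite_difference = fd_solve(st, params, opts, init))
}
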