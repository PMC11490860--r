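test_that("baseline parameters carry the documented defaults", {
  p <- model_params()
  expect_s3_class(p, "model_params")
  expect_equal(p$M, 1)
  expect_equal(p$alpha, 0.2)
  expect_equal(p$eps, 0.1)
  expect_equal(p$delta, 0.1)
  expect_equal(p$a, 0.3)
  expect_equal(p$b, 0.5)
  expect_equal(p$phi, pi / 3)
  expect_equal(p$Pr, 1)
  expect_equal(p$lambda1, 0.2)
  expect_equal(p$Da, 0.5)
  expect_equal(p$Br, 1)
  expect_equal(p$Gr, 0.5)
  expect_equal(p$Gm, 0.5)
  expect_equal(p$k, 1)
  expect_equal(p$Nt, 0.2)
  expect_equal(p$mu, 0.5)
  expect_equal(p$gamma1, 0.5)
  expect_equal(p$d1, 0.3)
  expect_equal(p$Nb, 0.5)
  expect_equal(p$d, 1)
  expect_equal(p$q, 1)
  expect_identical(p$bc_orientation, "lower_hot")
  expect_identical(p$uo_phase, "wavelength")
  expect_identical(p$joule_variant, "velocity")
})

test_that("parameter guards reject inadmissible values", {
  expect_error(model_params(Da = 0), "Da")
  expect_error(model_params(Da = -1), "Da")
  expect_error(model_params(Nb = 0, Nt = 0.2), "Nb")
  expect_error(model_params(mu = 0), "mu")
  expect_error(model_params(gamma1 = -0.5), "gamma1")
  expect_error(model_params(d1 = 0), "d1")
  expect_error(model_params(lambda1 = -1), "lambda1")
  expect_error(model_params(M = -0.1), "M")
  expect_error(model_params(Pr = -1), "Pr")
  expect_error(model_params(Br = -1), "Br")
  expect_error(model_params(Nt = -0.1), "Nt")
  expect_error(model_params(a = -0.1), "amplitudes")
  expect_error(model_params(d = 0), "half-width")
  expect_error(model_params(phi = -0.1), "phi")
  expect_error(model_params(phi = 4), "phi")
  expect_error(model_params(M = NA_real_), "finite")
})

test_that("Nb = 0 is admissible only with Nt = 0", {
  p <- model_params(Nb = 0, Nt = 0)
  expect_s3_class(p, "model_params")
  expect_error(model_params(Nb = 0, Nt = 0.1), "Nb")
})

test_that("wall non-contact admissibility bound is enforced", {
  # a^2 + b^2 + 2ab cos(phi) must not exceed (1+d)^2
  expect_error(model_params(a = 2, b = 2, d = 1, phi = 0), "admissibility")
  # large amplitudes pass while a + b stays below 1 + d
  p <- model_params(a = 0.5, b = 1.2, d = 1, phi = 0)
  expect_s3_class(p, "model_params")
  # same amplitudes with a shallower channel fail
  expect_error(model_params(a = 0.5, b = 1.2, d = 0.5, phi = 0),
               "admissibility")
})

test_that("wall positions follow the two-wave envelope", {
  p <- model_params()
  w <- wall_positions(0, p)
  expect_equal(w$h1, 1 + 0.3)
  expect_equal(w$h2, -1 - 0.5 * cos(pi / 3))
  w4 <- wall_positions(c(0, 0.25, 0.5, 0.75), p)
  expect_equal(w4$h1, 1 + 0.3 * cos(2 * pi * c(0, 0.25, 0.5, 0.75)))
  expect_equal(w4$h2, -1 - 0.5 * cos(2 * pi * c(0, 0.25, 0.5, 0.75) + pi / 3))
  # walls never touch over a wavelength for admissible parameters
  xx <- seq(0, 1, length.out = 401)
  ww <- wall_positions(xx, p)
  expect_true(all(ww$h1 > ww$h2))
})

test_that("cilia slip velocity oscillates about -1 with the wall phase", {
  p <- model_params()
  expect_equal(cilia_velocity(0, p), -1 - 2 * pi * 0.2 * 0.1 * 0.1)
  expect_equal(cilia_velocity(0.25, p), -1)
  expect_equal(cilia_velocity(0.5, p), -1 + 2 * pi * 0.2 * 0.1 * 0.1)
  # literal phase convention uses cos(x)
  pl <- model_params(uo_phase = "literal")
  expect_equal(cilia_velocity(0.25, pl),
               -1 - 2 * pi * 0.2 * 0.1 * 0.1 * cos(0.25))
  # zero cilia length: rigid wall moving with the wave frame
  p0 <- model_params(alpha = 0)
  expect_equal(cilia_velocity(c(0, 0.3, 0.7), p0), rep(-1, 3))
})

test_that("station bundles geometry and slip and rejects degenerate gaps", {
  p <- model_params()
  st <- station(0.25, p)
  expect_s3_class(st, "station")
  expect_equal(st$h1, 1 + 0.3 * cos(pi / 2))
  expect_equal(st$h2, -1 - 0.5 * cos(pi / 2 + pi / 3))
  expect_equal(st$uo, cilia_velocity(0.25, p))
  expect_error(station(NA_real_, p))
})

test_that("right-hand side matches the hand-evaluated closures", {
  # decoupled check: only psi'' = 1 nonzero, Gr = Gm = 0
  p <- model_params(Gr = 0, Gm = 0)
  s <- numeric(10)
  s[3] <- 1
  d <- ode_rhs(0, s, p)
  c1 <- p$k * p$d1 / p$gamma1                       # 0.6
  expect_equal(unname(d["d_dw"]), c1 * (2 * 0 + 1)) # 0.6
  beta <- p$M^2 + 1 / p$Da                          # 3
  expect_equal(unname(d["d_d3psi"]),
               (1 + p$lambda1) * (beta * 1 - (p$k / p$mu) * c1)) # 2.16
  # energy: -Br (1/(1.2)) - Br M^2 (0+1)^2 = -1/1.2 - 1
  expect_equal(unname(d["d_dtheta"]), -1 / 1.2 - 1)
  expect_equal(unname(d["d_domega"]), (0.2 / 0.5) * (1 / 1.2 + 1))
  # chain components
  expect_equal(unname(d["d_psi"]), s[2])
  expect_equal(unname(d["d_u"]), s[3])
  expect_equal(unname(d["d_theta"]), s[6])
  expect_equal(unname(d["d_omega"]), s[8])
  expect_equal(unname(d["d_w"]), s[10])
})

test_that("Joule-heating variant switches the dissipation argument", {
  s <- numeric(10)
  s[2] <- 0.5   # u
  s[3] <- 2     # du/dy
  pv <- model_params(Gr = 0, Gm = 0, joule_variant = "velocity")
  ps <- model_params(Gr = 0, Gm = 0, joule_variant = "shear")
  dv <- ode_rhs(0, s, pv)[["d_dtheta"]]
  ds <- ode_rhs(0, s, ps)[["d_dtheta"]]
  A1 <- 1.2
  expect_equal(dv, -1 * (4 / A1 + 1 * (0.5 + 1)^2))
  expect_equal(ds, -1 * (4 / A1 + 1 * (2 + 1)^2))
})

test_that("analytic state Jacobian matches central differences", {
  p <- model_params(M = 2, Gr = 1.5, Gm = 0.7, Br = 2, Pr = 3, Nt = 0.4)
  set.seed(42)
  s <- rnorm(10)
  J <- ciliaflow:::rhs_jac(matrix(s, 10), p)[, , 1]
  f <- function(x) drop(ciliaflow:::rhs_mat(matrix(x, 10), p))
  Jn <- vapply(1:10, function(j) num_jac_col(f, s, j), numeric(10))
  expect_lt(max(abs(J - Jn)), 1e-6)
  # and for the shear Joule variant
  p2 <- model_params(M = 2, joule_variant = "shear")
  J2 <- ciliaflow:::rhs_jac(matrix(s, 10), p2)[, , 1]
  f2 <- function(x) drop(ciliaflow:::rhs_mat(matrix(x, 10), p2))
  J2n <- vapply(1:10, function(j) num_jac_col(f2, s, j), numeric(10))
  expect_lt(max(abs(J2 - J2n)), 1e-6)
})

test_that("boundary-condition residuals vanish exactly on target states", {
  p <- model_params()
  st <- station(0, p)
  lo <- numeric(10); hi <- numeric(10)
  lo[1] <- -p$q / 2; lo[2] <- st$uo; lo[5] <- 1; lo[7] <- 1; lo[9] <- 0
  hi[1] <- p$q / 2;  hi[2] <- st$uo; hi[5] <- 0; hi[7] <- 0; hi[9] <- 0
  r <- bc_residuals(lo, hi, st, p)
  expect_equal(unname(r), rep(0, 10))
  # perturbation appears in exactly the right slot
  lo[5] <- 1.25
  r2 <- bc_residuals(lo, hi, st, p)
  expect_equal(unname(r2[["theta_lower"]]), 0.25)
  expect_equal(sum(r2 != 0), 1L)
})

test_that("orientation flag flips the heated wall", {
  p <- model_params(bc_orientation = "upper_hot")
  st <- station(0, p)
  lo <- numeric(10); hi <- numeric(10)
  lo[1] <- -p$q / 2; lo[2] <- st$uo
  hi[1] <- p$q / 2;  hi[2] <- st$uo; hi[5] <- 1; hi[7] <- 1
  r <- bc_residuals(lo, hi, st, p)
  expect_equal(unname(r), rep(0, 10))
})

test_that("first integral of the concentration closure holds pointwise", {
  # Omega'' + (Nt/Nb) theta'' = 0 for every state, any parameters
  set.seed(7)
  for (rep in 1:5) {
    p <- model_params(Nt = runif(1, 0, 1), Nb = runif(1, 0.2, 1),
                      M = runif(1, 0, 3), Br = runif(1, 0, 3))
    s <- rnorm(10)
    d <- ciliaflow:::rhs_mat(matrix(s, 10), p)
    expect_equal(d[8, 1] + (p$Nt / p$Nb) * d[6, 1], 0)
  }
})
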