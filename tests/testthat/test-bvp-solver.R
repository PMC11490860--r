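# Solver correctness against closed forms and cross-solver agreement.

test_that("collocation reproduces plane Poiseuille flow in the decoupled limit", {
  p <- model_params(Gr = 0, Gm = 0, k = 0, M = 0, Da = 1e9, lambda1 = 0,
                    alpha = 0, a = 0, b = 0, d = 1, q = 1)
  st <- station(0, p)
  sol <- solve_station(st, p, solver_options())
  expect_true(sol$converged)
  # closed form: u(0) = 1.25, dp/dx = -4.5 for q = 1, walls at +/-1, uo = -1
  expect_equal(unname(center_values(sol)[["u"]]), 1.25, tolerance = 1e-9)
  pg <- pressure_gradient(sol, p)
  expect_equal(pg$dpdx_mean, -4.5, tolerance = 1e-8)
})

test_that("rigid translation: q = -2 gives a uniform stream u = -1", {
  # With uo = -1 at both walls (alpha = 0) and q = -(h1 - h2) the exact
  # solution is rigid motion with the wave frame; dp/dx = 0.
  p <- model_params(Gr = 0, Gm = 0, k = 0, M = 0, Da = 1e9, lambda1 = 0,
                    alpha = 0, a = 0, b = 0, d = 1, q = -2)
  st <- station(0, p)
  sol <- solve_station(st, p, solver_options())
  expect_lt(max(abs(sol$states[, "u"] + 1)), 1e-9)
  pg <- pressure_gradient(sol, p)
  expect_lt(abs(pg$dpdx_mean), 1e-9)
})

test_that("all three solvers match the cosh/sinh closed form when decoupled", {
  p <- model_params(Gr = 0, Gm = 0, k = 0, M = 2, Da = 0.5, lambda1 = 0.2)
  st <- station(0, p)
  ana <- analytic_limit_solution(st, p)
  sc <- solve_station(st, p, solver_options())
  expect_lt(max(abs(sc$states[, "u"] - ana$u(sc$y_grid))), 1e-8)
  sh <- shooting_solve(st, p, solver_options(method = "shooting"))
  expect_lt(max(abs(sh$states[, "u"] - ana$u(sh$y_grid))), 1e-7)
  sf <- fd_solve(st, p, solver_options(method = "finite_difference",
                                       initial_mesh_n = 801L))
  expect_lt(max(abs(sf$states[, "u"] - ana$u(sf$y_grid))), 1e-4)
})

test_that("collocation and shooting agree on the fully coupled baseline", {
  p <- model_params()
  st <- station(0, p)
  sc <- cached("baseline", solve_station(st, p, solver_options()))
  sh <- cached("baseline_shoot",
               shooting_solve(st, p, solver_options(method = "shooting")))
  yy <- seq(st$h2, st$h1, length.out = 201)
  d <- max(abs(interpolate_solution(sc, yy) - interpolate_solution(sh, yy)))
  expect_lt(d, 1e-6)
})

test_that("boundary conditions are satisfied to solver tolerance", {
  sol <- baseline_solution()
  p <- model_params()
  r <- bc_residuals(sol$states[1, ], sol$states[sol$mesh_n, ],
                    sol$station, p)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("solution is deterministic: identical repeated solves", {
  p <- model_params()
  st <- station(0, p)
  s1 <- solve_station(st, p, solver_options())
  s2 <- solve_station(st, p, solver_options())
  expect_identical(s1$states, s2$states)
  expect_identical(s1$y_grid, s2$y_grid)
})

test_that("warm start reproduces the cold-start solution", {
  p <- model_params()
  st <- station(0, p)
  cold <- baseline_solution()
  p2 <- model_params(M = 1.2)
  warm <- solve_station(st, p2, solver_options(), init = cold)
  cold2 <- solve_station(st, p2, solver_options())
  yy <- seq(st$h2, st$h1, length.out = 101)
  expect_lt(max(abs(interpolate_solution(warm, yy) -
                      interpolate_solution(cold2, yy))), 1e-6)
})

test_that("mesh refinement reduces the collocation error estimate", {
  p <- model_params()
  sol <- baseline_solution()
  expect_true(sol$converged)
  expect_lte(sol$residual_norm, solver_options()$tolerance)
  expect_gt(sol$mesh_n, solver_options()$initial_mesh_n)
})

test_that("continuation rescues a hard cold start", {
  p <- model_params(Gr = 2, Gm = 2, Br = 3)
  st <- station(0, p)
  sol <- robust_solve(st, p, solver_options())
  expect_true(sol$converged)
  a <- invariant_audit(sol, p)
  expect_lt(a$max_bc_residual, 1e-8)
})

test_that("non-convergence raises a structured condition", {
  p <- model_params()
  st <- station(0, p)
  # an impossible budget forces a convergence failure, not a crash
  expect_error(
    solve_station(st, p, solver_options(max_mesh = 8L, initial_mesh_n = 5L)),
    class = "ciliaflow_convergence_error")
})

test_that("initial guess satisfies the boundary conditions exactly", {
  p <- model_params()
  st <- station(0, p)
  g <- ciliaflow:::initial_guess(st, p, 21L)
  r <- bc_residuals(g$states[1, ], g$states[21, ], st, p)
  # psi-family conditions are met by the cubic; theta/omega by the linear ramp
  expect_lt(max(abs(r)), 1e-12)
})

test_that("finite-difference solver is second-order accurate", {
  p <- model_params(Gr = 0, Gm = 0, k = 0, M = 2, Da = 0.5, lambda1 = 0.2)
  st <- station(0, p)
  ana <- analytic_limit_solution(st, p)
  errs <- vapply(c(101L, 201L), function(n) {
    s <- fd_solve(st, p, solver_options(method = "finite_difference",
                                        initial_mesh_n = n))
    max(abs(s$states[, "u"] - ana$u(s$y_grid)))
  }, numeric(1))
  expect_gt(log2(errs[1] / errs[2]), 1.8)
})

test_that("solver dispatch honours the method option", {
  p <- model_params()
  st <- station(0, p)
  s1 <- solve_station(st, p, solver_options(method = "collocation"))
  expect_identical(s1$method, "collocation")
  s3 <- solve_station(st, p, solver_options(method = "finite_difference"))
  expect_identical(s3$method, "finite_difference")
})

test_that("analytic limit solution rejects coupled parameters", {
  p <- model_params()   # Gr, Gm, k nonzero
  st <- station(0, p)
  expect_error(analytic_limit_solution(st, p))
})
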