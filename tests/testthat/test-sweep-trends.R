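# Parameter sweeps and monotonicity verdicts.

test_that("sweep_spec validates every varied value before any solve", {
  base <- model_params()
  expect_s3_class(sweep_spec(base, list(M = c(0, 1, 2, 3))), "sweep_spec")
  expect_error(sweep_spec(base, list(Da = c(0.5, 0))), "Da")
  expect_error(sweep_spec(base, list(a = 2)), "admissibility")
  expect_error(sweep_spec(base, list(zz = 1)), "unknown sweep parameter")
  expect_error(sweep_spec(base, list(1:3)), "named")
})

test_that("empty vary list produces a single baseline row", {
  sw <- cached("sweep_empty",
               run_sweep(sweep_spec(model_params()), solver_options()))
  expect_equal(nrow(sw), 1L)
  expect_true(sw$converged)
  cv <- center_values(baseline_solution())
  expect_equal(sw$u_c, unname(cv[["u"]]), tolerance = 1e-8)
})

test_that("M sweep yields one converged row per value with stable columns", {
  sw <- cached("sweep_M", {
    sp <- sweep_spec(model_params(), list(M = c(0, 1, 2, 3)), stations = 0)
    run_sweep(sp, solver_options())
  })
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$converged))
  expect_identical(
    names(sw),
    c("parameter", "value", "x", "converged", "u_c", "theta_c", "omega_c",
      "w_c", "cf_h1", "cf_h2", "nu_h1", "nu_h2", "sh_h1", "sh_h2",
      "dpdx_mean", "dpdx_dev", "residual_norm", "mesh_n", "method"))
})

test_that("Lorentz drag decelerates the bulk flow and Joule heating warms it", {
  sw <- cached("sweep_M", {
    sp <- sweep_spec(model_params(), list(M = c(0, 1, 2, 3)), stations = 0)
    run_sweep(sp, solver_options())
  })
  tr <- trend_report(sw)
  vu <- tr[tr$parameter == "M" & tr$quantity == "u_c", ]
  vt <- tr[tr$parameter == "M" & tr$quantity == "theta_c", ]
  expect_identical(vu$verdict, "decreasing")
  expect_identical(vt$verdict, "increasing")
  expect_true(vu$matches); expect_true(vt$matches)
  expect_true(vu$assert); expect_true(vt$assert)
})

test_that("verdicts are invariant under sweep-order reversal", {
  sw <- cached("sweep_M", {
    sp <- sweep_spec(model_params(), list(M = c(0, 1, 2, 3)), stations = 0)
    run_sweep(sp, solver_options())
  })
  sw_rev <- sw[rev(seq_len(nrow(sw))), ]
  class(sw_rev) <- class(sw)
  tr1 <- trend_report(sw)
  tr2 <- trend_report(sw_rev)
  expect_identical(tr1$verdict, tr2$verdict)
})

test_that("re-solving a sweep row cold reproduces its recorded values", {
  sw <- cached("sweep_M", {
    sp <- sweep_spec(model_params(), list(M = c(0, 1, 2, 3)), stations = 0)
    run_sweep(sp, solver_options())
  })
  p <- model_params(M = 3)
  sol <- solve_station(station(0, p), p, solver_options())
  cv <- center_values(sol)
  row <- sw[sw$value == 3, ]
  expect_equal(row$u_c, unname(cv[["u"]]), tolerance = 1e-7)
  expect_equal(row$theta_c, unname(cv[["theta"]]), tolerance = 1e-7)
})

test_that("verdict classification is exact on synthetic sequences", {
  expect_identical(ciliaflow:::verdict_of(c(1, 2, 3)), "increasing")
  expect_identical(ciliaflow:::verdict_of(c(3, 2, 1)), "decreasing")
  expect_identical(ciliaflow:::verdict_of(c(1, 1, 1)), "constant")
  expect_identical(ciliaflow:::verdict_of(c(1, 2, 1)), "non-monotone")
  # NA rows (failed solves) are dropped before classification
  expect_identical(ciliaflow:::verdict_of(c(1, NA, 3)), "increasing")
  expect_identical(ciliaflow:::verdict_of(c(NA, 2, NA)), "constant")
})

test_that("trend_report requires at least three values per parameter", {
  sp <- sweep_spec(model_params(), list(M = c(0, 1)), stations = 0)
  sw <- run_sweep(sp, solver_options())
  expect_error(trend_report(sw), ">= 3 values")
})

test_that("expected-trend table asserts only orientation-robust claims", {
  et <- expected_trends()
  hard <- et[et$assert, ]
  expect_setequal(paste(hard$parameter, hard$quantity),
                  c("M u_c", "M theta_c", "Pr omega_c"))
  # buoyancy-direction rows are present but report-only
  expect_true(all(!et$assert[et$parameter %in% c("Gr", "Gm", "Da")]))
})

test_that("sweep CSV round-trips numerically at %.12g", {
  sw <- cached("sweep_empty",
               run_sweep(sweep_spec(model_params()), solver_options()))
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  back <- utils::read.csv(f)
  expect_equal(back$u_c, sw$u_c, tolerance = 1e-11)
  expect_equal(back$dpdx_mean, sw$dpdx_mean, tolerance = 1e-11)
  # byte-identical on rewrite
  f2 <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f2)
  expect_identical(readLines(f), readLines(f2))
  unlink(c(f, f2))
})
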