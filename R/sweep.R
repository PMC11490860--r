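#' Specify a parameter sweep
#'
#' @param base the baseline \code{model_params}.
#' @param vary named list: each element is the numeric vector of values for
#'   the parameter of that name (an empty list gives a single baseline row).
#' @param stations numeric vector of axial positions (default 0).
#' @return An object of class \code{"sweep_spec"}. Every varied value is
#'   validated for admissibility up front; an inadmissible value is an
#'   error before any solve.
#' @export
sweep_spec <- function(base, vary = list(), stations = 0) {
  validate_params(base)
  stopifnot(is.list(vary))
  if (length(vary) && is.null(names(vary)))
    stop("vary must be a named list of parameter-value vectors",
         call. = FALSE)
  for (nm in names(vary)) {
    if (!nm %in% names(base) || !is.numeric(base[[nm]]))
      stop("unknown sweep parameter '", nm, "'", call. = FALSE)
    for (v in vary[[nm]]) {
      p <- base; p[[nm]] <- v
      validate_params(p)
      for (x in stations) station(x, p)   # wall admissibility at stations
    }
  }
  sp <- list(base = base, vary = vary, stations = stations)
  class(sp) <- "sweep_spec"
  sp
}

#' Run a parameter sweep
#'
#' Solves the boundary-value problem for every (parameter, value, station)
#' combination of the sweep specification, warm-starting each solve from the previous
#' value of the same parameter, and tabulates centre-line values, wall
#' fluxes and the axial pressure gradient. Non-converged rows are flagged
#' (\code{converged = FALSE}, quantities \code{NA}), never dropped.
#'
#' @param spec a \code{\link{sweep_spec}}.
#' @param opts a \code{\link{solver_options}} object.
#' @return A \code{data.frame} (class \code{"sweep_result"}) with one row
#'   per combination: \code{parameter, value, x, converged, u_c, theta_c,
#'   omega_c, w_c, cf_h1, cf_h2, nu_h1, nu_h2, sh_h1, sh_h2, dpdx_mean,
#'   dpdx_dev, residual_norm, mesh_n, method}.
#' @export
run_sweep <- function(spec, opts = solver_options()) {
  stopifnot(inherits(spec, "sweep_spec"))
  vary <- spec$vary
  if (!length(vary)) vary <- list(baseline = NA_real_)
  rows <- list()
  for (nm in names(vary)) {
    for (x in spec$stations) {
      warm <- NULL
      for (v in vary[[nm]]) {
        p <- spec$base
        if (!is.na(v)) p[[nm]] <- v
        st <- station(x, p)
        sol <- tryCatch(
          solve_station(st, p, opts, init = warm),
          ciliaflow_convergence_error = function(e)
            tryCatch(continuation_solve(st, p, opts),
                     ciliaflow_convergence_error = function(e2) NULL))
        if (is.null(sol)) {
          rows[[length(rows) + 1L]] <- data.frame(
            parameter = nm, value = v, x = x, converged = FALSE,
            u_c = NA_real_, theta_c = NA_real_, omega_c = NA_real_,
            w_c = NA_real_, cf_h1 = NA_real_, cf_h2 = NA_real_,
            nu_h1 = NA_real_, nu_h2 = NA_real_, sh_h1 = NA_real_,
            sh_h2 = NA_real_, dpdx_mean = NA_real_, dpdx_dev = NA_real_,
            residual_norm = NA_real_, mesh_n = NA_integer_,
            method = opts$method)
          warm <- NULL
          next
        }
        warm <- sol
        cv <- center_values(sol)
        wf <- wall_fluxes(sol, p)
        pg <- pressure_gradient(sol, p)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = nm, value = v, x = x, converged = TRUE,
          u_c = cv[["u"]], theta_c = cv[["theta"]],
          omega_c = cv[["omega"]], w_c = cv[["w"]],
          cf_h1 = wf$cf_h1, cf_h2 = wf$cf_h2,
          nu_h1 = wf$nu_h1, nu_h2 = wf$nu_h2,
          sh_h1 = wf$sh_h1, sh_h2 = wf$sh_h2,
          dpdx_mean = pg$dpdx_mean, dpdx_dev = pg$dpdx_dev,
          residual_norm = sol$residual_norm, mesh_n = sol$mesh_n,
          method = sol$method)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Expected qualitative trends of the centre-line quantities
#'
#' The encoded expectation table used by \code{\link{trend_report}}:
#' for each swept parameter, the direction in which a centre-line quantity
#' should move. Orientation-robust physics (Lorentz drag decelerating the
#' bulk flow and Joule heating raising the temperature as \code{M} grows;
#' Prandtl-driven suppression of nanoparticle diffusion) are marked
#' \code{assert = TRUE}; buoyancy-direction claims, which flip with the
#' thermal boundary-condition orientation, are report-only.
#'
#' @return A \code{data.frame} with columns \code{parameter, quantity,
#'   expected, assert}.
#' @export
expected_trends <- function() {
  tab <- rbind(
    data.frame(parameter = "M", quantity = "u_c",
               expected = "decreasing", assert = TRUE),
    data.frame(parameter = "M", quantity = "theta_c",
               expected = "increasing", assert = TRUE),
    data.frame(parameter = "M", quantity = "omega_c",
               expected = "decreasing", assert = FALSE),
    data.frame(parameter = "Pr", quantity = "omega_c",
               expected = "decreasing", assert = TRUE),
    data.frame(parameter = "Pr", quantity = "theta_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "Gr", quantity = "u_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "Gr", quantity = "theta_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "Gr", quantity = "omega_c",
               expected = "decreasing", assert = FALSE),
    data.frame(parameter = "Gr", quantity = "w_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "Gm", quantity = "u_c",
               expected = "decreasing", assert = FALSE),
    data.frame(parameter = "Gm", quantity = "omega_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "Da", quantity = "theta_c",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "M", quantity = "dpdx_mean",
               expected = "decreasing", assert = FALSE),
    data.frame(parameter = "Da", quantity = "dpdx_mean",
               expected = "increasing", assert = FALSE),
    data.frame(parameter = "lambda1", quantity = "dpdx_mean",
               expected = "increasing", assert = FALSE))
  tab
}

verdict_of <- function(v, tol = 1e-10) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return("constant")
  d <- diff(v)
  scale <- max(1, max(abs(v)))
  if (all(abs(d) <= tol * scale)) return("constant")
  if (all(d > tol * scale)) return("increasing")
  if (all(d < -tol * scale)) return("decreasing")
  "non-monotone"
}

#' Monotonicity verdicts for a sweep
#'
#' For every (quantity, parameter, station) combination of a sweep result,
#' orders the rows by parameter value and classifies the centre-line and
#' wall quantities as strictly \code{increasing}, \code{decreasing},
#' \code{constant} or \code{non-monotone}, then compares against the
#' \code{\link{expected_trends}} table.
#'
#' @param sweep a \code{sweep_result} from \code{\link{run_sweep}} with at
#'   least 3 values per varied parameter.
#' @param expected expectation table (default \code{\link{expected_trends}()}).
#' @param quantities which columns to classify.
#' @return A \code{data.frame} (class \code{"trend_report"}) with columns
#'   \code{quantity, parameter, x, verdict, values, expected, matches,
#'   assert}; \code{expected/matches/assert} are \code{NA} for
#'   combinations without an encoded expectation.
#' @export
trend_report <- function(sweep, expected = expected_trends(),
                         quantities = c("u_c", "theta_c", "omega_c", "w_c",
                                        "cf_h1", "cf_h2", "nu_h1", "nu_h2",
                                        "sh_h1", "sh_h2", "dpdx_mean")) {
  stopifnot(inherits(sweep, "data.frame"))
  rows <- list()
  for (nm in unique(sweep$parameter)) {
    if (nm == "baseline") next
    for (x in unique(sweep$x)) {
      sub <- sweep[sweep$parameter == nm & sweep$x == x, , drop = FALSE]
      if (nrow(sub) < 3L)
        stop("trend_report needs >= 3 values per varied parameter (got ",
             nrow(sub), " for '", nm, "')", call. = FALSE)
      sub <- sub[order(sub$value), , drop = FALSE]
      for (qt in quantities) {
        vd <- verdict_of(sub[[qt]])
        exp_row <- expected[expected$parameter == nm &
                              expected$quantity == qt, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          quantity = qt, parameter = nm, x = x, verdict = vd,
          values = paste(signif(sub[[qt]], 8), collapse = ";"),
          expected = if (nrow(exp_row)) exp_row$expected[1L] else NA_character_,
          matches = if (nrow(exp_row)) vd == exp_row$expected[1L] else NA,
          assert = if (nrow(exp_row)) exp_row$assert[1L] else NA)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_report", "data.frame")
  out
}

#' Write a sweep result as a reproducible CSV
#'
#' Fixed column order, numbers formatted with \code{\%.12g} so that repeated
#' runs with identical inputs are byte-identical across platforms.
#'
#' @param sweep a \code{sweep_result}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- as.data.frame(sweep)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.12g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
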