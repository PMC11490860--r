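#' Load a run configuration
#'
#' Reads a declarative JSON (or YAML, if the \pkg{yaml} package is
#' installed and the file ends in \code{.yaml}/\code{.yml}) configuration
#' and returns a fully validated \code{run_config} with baseline defaults
#' filled in for every omitted field. Unknown keys anywhere in the file are
#' a hard error, reported with their key path.
#'
#' Recognised top-level keys: \code{params} (any \code{\link{model_params}}
#' numeric field), \code{flags} (\code{bc_orientation}, \code{uo_phase},
#' \code{joule_variant}), \code{stations}, \code{solver} (any
#' \code{\link{solver_options}} field), \code{sweep}
#' (\code{vary}: named lists of values; \code{stations}), and
#' \code{output_dir}.
#'
#' @param path path to the configuration file.
#' @return An object of class \code{"run_config"}: list with \code{params},
#'   \code{stations}, \code{solver}, \code{sweep} (a \code{sweep_spec} or
#'   \code{NULL}) and \code{output_dir}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg)) cfg <- list()
  run_config_from_list(cfg)
}

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(path, ".", bad, collapse = ", "), call. = FALSE)
}

#' Build a run configuration from a list
#'
#' The programmatic counterpart of \code{\link{load_config}}; applies the
#' same validation and default-filling to an in-memory list.
#'
#' @param cfg a (possibly empty) named list with the keys documented in
#'   \code{\link{load_config}}.
#' @return A \code{run_config}.
#' @export
run_config_from_list <- function(cfg) {
  stopifnot(is.list(cfg))
  check_keys(cfg, c("params", "flags", "stations", "solver", "sweep",
                    "output_dir"), "config")
  pdef <- formals(model_params)
  num_fields <- setdiff(names(pdef),
                        c("bc_orientation", "uo_phase", "joule_variant"))
  pargs <- list()
  if (!is.null(cfg$params)) {
    check_keys(cfg$params, num_fields, "config.params")
    pargs <- lapply(cfg$params, as.numeric)
  }
  if (!is.null(cfg$flags)) {
    check_keys(cfg$flags, c("bc_orientation", "uo_phase", "joule_variant"),
               "config.flags")
    pargs <- c(pargs, cfg$flags)
  }
  params <- do.call(model_params, pargs)
  stations_x <- if (is.null(cfg$stations)) 0 else as.numeric(cfg$stations)
  sargs <- list()
  if (!is.null(cfg$solver)) {
    check_keys(cfg$solver, names(formals(solver_options)), "config.solver")
    sargs <- cfg$solver
  }
  solver <- do.call(solver_options, sargs)
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    check_keys(cfg$sweep, c("vary", "stations"), "config.sweep")
    vv <- lapply(cfg$sweep$vary, as.numeric)
    sw_st <- if (is.null(cfg$sweep$stations)) stations_x
             else as.numeric(cfg$sweep$stations)
    sweep <- sweep_spec(params, vary = vv, stations = sw_st)
  }
  rc <- list(params = params, stations = stations_x, solver = solver,
             sweep = sweep,
             output_dir = if (is.null(cfg$output_dir)) "."
                          else as.character(cfg$output_dir))
  class(rc) <- "run_config"
  rc
}

#' Serialise a run configuration
#'
#' Writes a \code{run_config} back to JSON such that
#' \code{load_config(save_config(rc, f))} reproduces it exactly
#' (lossless round trip).
#'
#' @param rc a \code{run_config}.
#' @param path output path (JSON).
#' @return \code{path}, invisibly.
#' @export
save_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  p <- rc$params
  num <- vapply(p, is.numeric, logical(1L))
  out <- list(
    params = p[num],
    flags = list(bc_orientation = p$bc_orientation,
                 uo_phase = p$uo_phase,
                 joule_variant = p$joule_variant),
    stations = rc$stations,
    solver = unclass(rc$solver),
    output_dir = rc$output_dir)
  if (!is.null(rc$sweep))
    out$sweep <- list(vary = rc$sweep$vary, stations = rc$sweep$stations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
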