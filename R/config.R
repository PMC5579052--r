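## Run configuration and the programmatic back end of the command-line
## front end. A run config is a small YAML file; unknown keys are rejected
## (typo safety), defaults are filled in, and paths are resolved relative
## to the config file's location.

.config_keys <- c("cluster_set", "pressure", "temperature", "parameters",
                  "parameters_file", "fit", "output_dir", "verbosity",
                  "seed", "kinetics_csv", "kw_mode", "xyz", "probe",
                  "spacing", "volume_mode")

.pressure_Pa <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))          # bare number: Pa
  stopifnot(is.list(p), !is.null(p$value))
  unit <- if (is.null(p$unit)) "Pa" else p$unit
  p$value * switch(unit, Pa = 1, atm = .const$atm_Pa, bar = .const$bar_Pa,
                   stop("unknown pressure unit '", unit, "' (Pa, atm, bar)"))
}

#' Parse a run-configuration file
#'
#' Reads a YAML run configuration, rejects unknown keys, validates the
#' temperature grid and pressure, resolves the cluster-set (and any other)
#' path relative to the config file, and fills in defaults: pressure 1 atm,
#' temperature grid 274 to 400 K in 1 K steps, verbosity 1, seed 1, output
#' directory \code{"qce_out"}.
#'
#' Recognized keys: \code{cluster_set} (required), \code{pressure}
#' (\code{value} + \code{unit} in atm/Pa/bar, or a bare number in Pa),
#' \code{temperature} (\code{start}, \code{stop}, \code{step} in K),
#' \code{parameters} (\code{a_mf}, \code{b_xv}) or \code{parameters_file}
#' (YAML written by the \code{fit} subcommand), \code{fit} (arguments of
#' [fit_spec()]), \code{output_dir}, \code{verbosity}, \code{seed},
#' \code{kinetics_csv}, \code{kw_mode}, \code{xyz}, \code{probe},
#' \code{spacing}, \code{volume_mode}.
#'
#' @param path Path to the YAML config.
#' @return Object of class \code{"qce_run_config"}.
#' @seealso [run_subcommand()], [write_run_config()]
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$cluster_set)) stop("config is missing the cluster-set path")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|~)", p)) p else file.path(base, p)
  }
  tg <- raw$temperature
  if (is.null(tg)) tg <- list(start = 274, stop = 400, step = 1)
  for (k in c("start", "stop", "step"))
    if (is.null(tg[[k]])) stop("temperature grid needs start, stop and step")
  if (tg$step <= 0) stop("temperature grid step must be > 0")
  if (tg$stop < tg$start) stop("temperature grid stop must be >= start")
  if (!is.null(raw[["parameters"]]) && !is.null(raw[["parameters_file"]]))
    stop("give either explicit parameters or a parameters_file, not both")
  cfg <- list(
    cluster_set = resolve(raw$cluster_set),
    pressure = .pressure_Pa(if (is.null(raw$pressure))
      list(value = 1, unit = "atm") else raw$pressure),
    temperature = list(start = tg$start, stop = tg$stop, step = tg$step),
    parameters = raw[["parameters"]],
    parameters_file = resolve(raw[["parameters_file"]]),
    fit = raw$fit,
    output_dir = if (is.null(raw$output_dir)) file.path(base, "qce_out")
                 else resolve(raw$output_dir),
    verbosity = if (is.null(raw$verbosity)) 1L else as.integer(raw$verbosity),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    kinetics_csv = resolve(raw$kinetics_csv),
    kw_mode = if (is.null(raw$kw_mode)) "diagonal" else raw$kw_mode,
    xyz = resolve(raw$xyz),
    probe = if (is.null(raw$probe)) 1.4 else raw$probe,
    spacing = if (is.null(raw$spacing)) 0.05 else raw$spacing,
    volume_mode = if (is.null(raw$volume_mode)) "vdw" else raw$volume_mode)
  structure(cfg, class = "qce_run_config")
}

#' Write the effective run configuration back to YAML
#'
#' Dumps a parsed config (defaults filled, paths absolute) so that
#' re-parsing the dump reproduces the identical configuration.
#'
#' @param cfg A \code{"qce_run_config"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Serialize a converged state to JSON
#'
#' A documented flat JSON record: temperature (K), pressure (Pa), molar
#' volume (L/mol monomer), exclusion volume, phase, Helmholtz and Gibbs
#' energies (kJ/mol monomer), convergence data and the named per-cluster
#' populations (mol per mol monomer).
#'
#' @param state A \code{"qce_state"}.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when \code{path} is given).
#' @export
state_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "qce_state"))
  rec <- list(T = state$T, p = state$p, molar_volume = state$molar_volume,
              exclusion_volume = state$exclusion_volume, phase = state$phase,
              helmholtz_energy = state$helmholtz_energy,
              gibbs_energy = state$gibbs_energy,
              converged = state$converged, iterations = state$iterations,
              populations = as.list(state$populations))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

.log_line <- function(con, ..., verbosity = 1L, echo = TRUE) {
  msg <- sprintf(...)
  writeLines(msg, con)
  if (echo && verbosity > 0L) message(msg)
}

#' Run one pipeline subcommand
#'
#' The programmatic core of the command-line tool. Subcommands:
#' \describe{
#'   \item{fit}{calibrate (a_mf, b_xv) per the config's \code{fit} section
#'     and write \code{fitted_parameters.yaml}.}
#'   \item{isobar}{temperature sweep; writes \code{isobar.csv} (T, molar
#'     volume, density, phase, Gibbs energy, per-cluster populations).}
#'   \item{kw}{ionic-product curve; writes \code{kw.csv} (T, Kw, pKw).}
#'   \item{kinetics}{step energetics of a stationary-point CSV; writes
#'     \code{barriers.csv}.}
#'   \item{volume}{grid volume of an XYZ geometry; writes
#'     \code{volume.txt}.}
#' }
#' Every run writes \code{effective_config.yaml} and an execution log
#' \code{qce_run.log} (package version, seed, parameters, convergence
#' warnings) into the config's output directory.
#'
#' @param name One of \code{"fit"}, \code{"isobar"}, \code{"kw"},
#'   \code{"kinetics"}, \code{"volume"}.
#' @param config A \code{"qce_run_config"} (or a path to one).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_subcommand <- function(name = c("fit", "isobar", "kw", "kinetics",
                                    "volume"), config) {
  name <- match.arg(name)
  if (is.character(config)) config <- parse_run_config(config)
  stopifnot(inherits(config, "qce_run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  logf <- file(out("qce_run.log"), "w")
  on.exit(close(logf))
  v <- config$verbosity
  .log_line(logf, "qcewater %s | subcommand %s | seed %d | %s",
            as.character(utils::packageVersion("qcewater")), name,
            config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
            verbosity = v)
  write_run_config(config, out("effective_config.yaml"))
  artifacts <- list(log = out("qce_run.log"),
                    config = out("effective_config.yaml"))
  set.seed(config$seed)

  params_from_config <- function() {
    if (!is.null(config$parameters))
      return(qce_parameters(config$parameters$a_mf, config$parameters$b_xv))
    if (!is.null(config$parameters_file)) {
      p <- yaml::read_yaml(config$parameters_file)
      return(qce_parameters(p$a_mf, p$b_xv))
    }
    stop("subcommand '", name,
         "' needs explicit parameters or a parameters_file; run 'fit' first")
  }
  grid <- with(config$temperature, seq(start, stop, by = step))

  if (name == "volume") {
    if (is.null(config$xyz)) stop("volume subcommand needs an xyz path")
    vol <- cluster_volume(config$xyz, probe = config$probe,
                          spacing = config$spacing, mode = config$volume_mode)
    writeLines(sprintf("%.6f", vol), out("volume.txt"))
    .log_line(logf, "volume(%s) = %.4f A^3 (spacing %.3g A, mode %s)",
              config$xyz, vol, config$spacing, config$volume_mode,
              verbosity = v)
    artifacts$volume <- out("volume.txt")
    return(invisible(artifacts))
  }
  if (name == "kinetics") {
    prof <- if (is.null(config$kinetics_csv)) read_reaction_profile()
            else read_reaction_profile(config$kinetics_csv)
    tab <- reaction_barriers(prof)
    utils::write.csv(tab, out("barriers.csv"), row.names = FALSE)
    .log_line(logf, "kinetics: %d steps, max barrier %.2f kcal/mol",
              nrow(tab), max(tab$dG0_kcal), verbosity = v)
    artifacts$barriers <- out("barriers.csv")
    return(invisible(artifacts))
  }

  cs <- load_cluster_set(config$cluster_set)
  .log_line(logf, "cluster set '%s': %d clusters", cs$name,
            length(cs$clusters), verbosity = v)
  if (name == "fit") {
    fit_cfg <- config$fit
    grid_n <- if (!is.null(fit_cfg$grid_n)) unlist(fit_cfg$grid_n) else c(20L, 20L)
    maxit <- if (!is.null(fit_cfg$maxit)) fit_cfg$maxit else 200L
    fit_cfg$grid_n <- NULL; fit_cfg$maxit <- NULL
    fs <- do.call(fit_spec, c(fit_cfg, list(pressure = config$pressure)))
    fit <- fit_qce(cs, fs, seed = config$seed, grid_n = grid_n, maxit = maxit)
    yaml::write_yaml(list(a_mf = fit$params$a_mf, b_xv = fit$params$b_xv,
                          objective = fit$objective,
                          density = fit$density,
                          density_error = fit$density_error,
                          boiling_T = fit$boiling_T,
                          boiling_error = fit$boiling_error,
                          seed = fit$seed),
                     out("fitted_parameters.yaml"), precision = 15L)
    .log_line(logf,
              "fit: a_mf = %.6g, b_xv = %.6g, objective %.3g, rho err %.3g, Tb err %.3g",
              fit$params$a_mf, fit$params$b_xv, fit$objective,
              fit$density_error, fit$boiling_error, verbosity = v)
    artifacts$fitted_parameters <- out("fitted_parameters.yaml")
    return(invisible(artifacts))
  }
  ## isobar / kw
  params <- params_from_config()
  iso <- withCallingHandlers(
    qce(cs, params, T = grid, p = config$pressure),
    warning = function(w) {
      .log_line(logf, "warning: %s", conditionMessage(w), verbosity = v,
                echo = FALSE)
      invokeRestart("muffleWarning")
    })
  .log_line(logf, "isobar: %d points, transition %s K", length(grid),
            format(iso$transition_temperature), verbosity = v)
  if (name == "isobar") {
    utils::write.csv(as.data.frame(iso), out("isobar.csv"), row.names = FALSE)
    artifacts$isobar <- out("isobar.csv")
  } else {
    utils::write.csv(kw_curve(iso, mode = config$kw_mode), out("kw.csv"),
                     row.names = FALSE)
    artifacts$kw <- out("kw.csv")
  }
  invisible(artifacts)
}
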