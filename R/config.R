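#' Default run configuration
#'
#' Nested configuration with every model default baked in, so a zero-argument
#' [run_simulate()] reproduces the headline co-medication scenario (reference
#' patient, rivaroxaban 15 mg bid + rifampin 600 mg qd for 22 days).
#'
#' Blocks: `induction`, `rifampin`, `rivaroxaban` (drug parameters),
#' `patient`, `cohort` (synthetic-study spec), `regimens` (per-drug dose,
#' frequency, days, start day), `solver` (`dt` h, `horizon_days`), `window`
#' (exposure bounds) and `seed`.
#'
#' @return A named list (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    induction = unclass(induction_params()),
    rifampin = unclass(rifampin_params()),
    rivaroxaban = unclass(rivaroxaban_params()),
    patient = unclass(reference_patient()),
    cohort = unclass(cohort_spec()),
    regimens = list(
      rivaroxaban = list(dose = 15, freq = "bid", days = 22, start_day = 1),
      rifampin = list(dose = 600, freq = "qd", days = 22, start_day = 1)),
    solver = list(dt = 0.05, horizon_days = 22),
    window = unclass(exposure_window()),
    seed = 20210723L
  ), class = "run_config")
}

# recursive schema check: every key in `cfg` must exist in `ref`
check_config_names <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("run_config: unknown key(s) ", paste0(path, extra, collapse = ", "))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]))
      check_config_names(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  invisible(TRUE)
}

# fill missing fields from the defaults, one block level deep
merge_config <- function(cfg, ref) {
  for (nm in names(ref)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- ref[[nm]]
    } else if (is.list(ref[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- merge_config(cfg[[nm]], ref[[nm]])
    }
  }
  cfg[names(ref)]
}

#' Read and validate a run configuration
#'
#' Reads YAML (`.yml`/`.yaml`) or JSON configuration. The top-level blocks of
#' [default_config()] must all be present; unknown keys anywhere are rejected
#' with their path; missing fields inside a block fall back to the defaults.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A bare list with (a subset of the fields of) the
#'   [default_config()] blocks.
#' @export
as_run_config <- function(cfg) {
  ref <- default_config()
  check_config_names(cfg, ref)
  missing_blocks <- setdiff(names(ref), names(cfg))
  if (length(missing_blocks))
    stop("run_config: missing required block(s): ",
         paste(missing_blocks, collapse = ", "))
  cfg <- merge_config(cfg, ref)
  structure(cfg, class = "run_config")
}

# ---- constructors from a config ------------------------------------------

config_params <- function(config) {
  ddi_params(do.call(induction_params, config$induction),
             do.call(rifampin_params, config$rifampin),
             do.call(rivaroxaban_params, config$rivaroxaban))
}

config_patient <- function(config) do.call(patient, config$patient)

config_regimen <- function(block) {
  regimen_pattern(block$dose, block$freq, block$days,
                  start = 24 * (block$start_day - 1))
}

#' Run a simulation from a configuration and write its outputs
#'
#' Simulates the configured scenario and writes `trajectory.csv` (tidy
#' time/state/value), `exposure.csv` and `exposure.json` (per-day metrics and
#' flags), and `manifest.json` (config echo, package version and seed, enough
#' to reproduce the run).
#'
#' @param config A `run_config` (default: [default_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `trajectory`, the `exposure` summary
#'   and the written `paths`.
#' @export
run_simulate <- function(config = default_config(), out_dir = tempfile("rivarif_")) {
  config <- as_run_config(unclass(config))
  params <- config_params(config)
  pat <- config_patient(config)
  traj <- simulate_ddi(pat, config_regimen(config$regimens$rivaroxaban),
                       config_regimen(config$regimens$rifampin),
                       t_end = config$solver$horizon_days * 24,
                       dt = config$solver$dt, params = params)
  window <- do.call(exposure_window, config$window)
  exposure <- daily_exposure(traj, window)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trajectory = file.path(out_dir, "trajectory.csv"),
                exposure_csv = file.path(out_dir, "exposure.csv"),
                exposure_json = file.path(out_dir, "exposure.json"),
                manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(as.data.frame(traj), paths$trajectory, row.names = FALSE)
  utils::write.csv(exposure, paths$exposure_csv, row.names = FALSE)
  jsonlite::write_json(list(
    days = exposure,
    steady_state = list(day = attr(exposure, "ss_day"),
                        cmax_ss = attr(exposure, "cmax_ss"),
                        auc_ss = attr(exposure, "auc_ss"))),
    paths$exposure_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(list(
    package = "rivarif",
    version = as.character(utils::packageVersion("rivarif")),
    seed = config$seed,
    config = unclass(config)),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(trajectory = traj, exposure = exposure, paths = paths))
}

#' Validate observed concentrations against the model
#'
#' Reads an observation table (`patient_id`, `time_h`, `conc_ng_ml`),
#' reconstructs the configured cohort and canonical scenario, and reports
#' per-point fold errors and the fraction below 2. Malformed rows are
#' rejected with their row numbers.
#'
#' @param config A `run_config`.
#' @param observations Path to an observations CSV, or a data.frame.
#' @param out_dir Optional directory; when given, `validation.json` is
#'   written there.
#' @return A [validation_report()] result.
#' @export
run_validate <- function(config = default_config(), observations,
                         out_dir = NULL) {
  config <- as_run_config(unclass(config))
  if (is.character(observations))
    observations <- utils::read.csv(observations)
  need <- c("patient_id", "time_h", "conc_ng_ml")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("run_validate: observation table lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(observations$time_h) |
                 !is.finite(observations$conc_ng_ml) |
                 observations$conc_ng_ml <= 0)
  if (length(bad))
    stop("run_validate: malformed observation row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  spec <- do.call(cohort_spec, config$cohort)
  study <- list(cohort = make_cohort(spec),
                observations = observations,
                scenario = synthetic_scenario(config$solver$horizon_days,
                                              spec$sampling_times))
  rep <- validation_report(study, config_params(config),
                           dt = config$solver$dt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(n = rep$n, fraction_lt2 = rep$fraction_lt2,
                              points = rep$points),
                         file.path(out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep
}

#' Run a dosing-regimen search from a configuration
#'
#' Dispatches to [evaluate_comedication_grid()], [plan_initiation()] or
#' [plan_withdrawal()] with the configured patient, parameters and window.
#' Infeasibility is reported as a structured result, never as an error.
#'
#' @param config A `run_config`.
#' @param mode One of `"comed"`, `"initiation"`, `"withdrawal"`.
#' @param out_dir Optional directory; when given, `recommendation.json` is
#'   written there.
#' @return The mode's recommendation object.
#' @export
run_optimize <- function(config = default_config(),
                         mode = c("comed", "initiation", "withdrawal"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  config <- as_run_config(unclass(config))
  params <- config_params(config)
  pat <- config_patient(config)
  window <- do.call(exposure_window, config$window)
  dt <- config$solver$dt
  res <- switch(mode,
    comed = evaluate_comedication_grid(patient = pat, params = params,
                                       window = window,
                                       rif_dose = config$regimens$rifampin$dose,
                                       horizon_days = config$solver$horizon_days,
                                       dt = dt),
    initiation = plan_initiation(patient = pat, params = params,
                                 window = window,
                                 rif_dose = config$regimens$rifampin$dose,
                                 horizon_days = config$solver$horizon_days,
                                 dt = dt),
    withdrawal = plan_withdrawal(patient = pat, params = params,
                                 window = window,
                                 rif_dose = config$regimens$rifampin$dose,
                                 dt = dt))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- switch(mode,
      comed = list(mode = mode, grid = res,
                   accepted = res$label[res$accepted]),
      initiation = list(mode = mode, feasible = res$feasible,
                        day1_dose = res$dose, day1_freq = res$freq,
                        table = res$table),
      withdrawal = list(mode = mode, schedule = res$schedule,
                        immediate = res$immediate,
                        maintained = res$maintained,
                        crossing_day = res$crossing_day))
    jsonlite::write_json(out, file.path(out_dir, "recommendation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
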