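# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic patient cohort
#'
#' Describes virtual patients with the characteristic ranges of the clinical
#' cases the analysis emulates (age 36-71 y, weight 60-67 kg, creatinine
#' clearance 52-129 ml/min, half male/half female), the residual-error model
#' for sparse observed concentrations, and the sampling design.
#'
#' @param n_patients Number of virtual patients (default 6).
#' @param age_range,weight_range,crcl_range Uniform sampling ranges
#'   (`c(lo, hi)`, `lo <= hi`).
#' @param sex_ratio Fraction of male patients (assigned deterministically as
#'   `round(n * sex_ratio)` males).
#' @param cv Lognormal residual-error coefficient of variation
#'   (dimensionless, >= 0).
#' @param sampling_times Sampling offsets after a dose (h).
#' @param seed Integer seed fixing all draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 6, age_range = c(36, 71),
                        weight_range = c(60, 67), crcl_range = c(52, 129),
                        sex_ratio = 0.5, cv = 0.2,
                        sampling_times = c(2, 4, 8, 12, 24),
                        seed = 20210723) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("cohort_spec: 'n_patients' must be >= 1")
  for (rg in list(age_range = age_range, weight_range = weight_range,
                  crcl_range = crcl_range)) {
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1] > rg[2] || rg[1] <= 0)
      stop("cohort_spec: ranges must be positive c(lo, hi) with lo <= hi")
  }
  if (cv < 0) stop("cohort_spec: 'cv' must be >= 0")
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("cohort_spec: 'sex_ratio' must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), age_range = age_range,
                 weight_range = weight_range, crcl_range = crcl_range,
                 sex_ratio = sex_ratio, cv = cv,
                 sampling_times = sampling_times,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a virtual patient cohort
#'
#' Draws patient covariates uniformly within the spec ranges; fully
#' deterministic given the spec's seed (the caller's RNG state is left
#' untouched).
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (class `cohort`) with columns `patient_id`, `age`,
#'   `weight`, `sex`, `crcl`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    n_male <- round(n * spec$sex_ratio)
    out <- data.frame(
      patient_id = seq_len(n),
      age = round(stats::runif(n, spec$age_range[1], spec$age_range[2])),
      weight = round(stats::runif(n, spec$weight_range[1],
                                  spec$weight_range[2]), 1),
      sex = c(rep("male", n_male), rep("female", n - n_male)),
      crcl = round(stats::runif(n, spec$crcl_range[1], spec$crcl_range[2])))
    class(out) <- c("cohort", "data.frame")
    out
  })
}

#' Convert a cohort row to a patient object
#'
#' @param cohort A `cohort` data.frame from [make_cohort()].
#' @param id Patient id (row).
#' @return A [patient()].
#' @export
cohort_patient <- function(cohort, id) {
  row <- cohort[cohort$patient_id == id, ]
  if (nrow(row) != 1L) stop("cohort_patient: unknown patient_id ", id)
  patient(row$age, row$weight, row$sex, row$crcl)
}

#' Canonical synthetic dosing scenario
#'
#' The fixture dosing history used for self-validation: rivaroxaban 10 mg qd
#' from day 1, rifampin 600 mg qd from day 4 through day 17, observed over
#' `days` days. This exercises the pre-induction, induction and washout
#' phases. Sampling days 1 (no rifampin), 7 and 14 (under induction) and 19
#' (washout) at the spec's post-dose offsets.
#'
#' @param days Scenario horizon in days.
#' @param sampling_times Post-dose sampling offsets (h).
#' @return A list with `riv_regimen`, `rif_regimen`, `t_end` (h) and
#'   `sample_times` (h).
#' @export
synthetic_scenario <- function(days = 21, sampling_times = c(2, 4, 8, 12, 24)) {
  sample_days <- c(1, 7, 14, 19)
  sample_days <- sample_days[sample_days <= days]
  st <- sort(unique(as.vector(outer(24 * (sample_days - 1), sampling_times,
                                    "+"))))
  n_rif <- min(14, max(0, days - 3))
  list(riv_regimen = regimen_qd(10, days),
       rif_regimen = if (n_rif > 0) regimen_qd(600, n_rif, start = 72)
                     else regimen(),
       t_end = days * 24,
       sample_times = st[st <= days * 24])
}

#' Sparse observations with multiplicative residual error
#'
#' Samples the model concentration at the requested times and applies a
#' lognormal residual: `obs = model * exp(e)` with
#' `e ~ N(0, sqrt(log(1 + cv^2)))`. Times at which the model concentration is
#' zero are skipped with a warning. Deterministic per seed.
#'
#' @param traj A `ddi_trajectory`.
#' @param times Sampling times (h) within the trajectory span.
#' @param cv Residual coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with `time_h`, `conc_ng_ml` (observed).
#' @export
make_observations <- function(traj, times, cv = 0.2, seed = 1) {
  stopifnot(inherits(traj, "ddi_trajectory"))
  if (any(times < min(traj$time)) || any(times > max(traj$time)))
    stop("make_observations: sampling times outside the trajectory span")
  pred <- stats::approx(traj$time, conc_rivaroxaban(traj), xout = times)$y
  keep <- pred > 0
  if (any(!keep)) {
    warning(sprintf(
      "make_observations: %d sample(s) at zero model concentration skipped",
      sum(!keep)))
    times <- times[keep]; pred <- pred[keep]
  }
  sigma <- sqrt(log(1 + cv^2))
  obs <- with_seed(seed, pred * exp(stats::rnorm(length(pred), 0, sigma)))
  data.frame(time_h = times, conc_ng_ml = obs)
}

#' Generate a complete synthetic study
#'
#' Builds a cohort, simulates the canonical scenario for each patient, and
#' samples sparse observations with the spec's residual error. Each patient's
#' draws use `spec$seed + patient_id` so the whole study is reproducible from
#' the spec alone.
#'
#' @param spec A [cohort_spec()].
#' @param params A [ddi_params()] bundle.
#' @param days Scenario horizon (days).
#' @param dt Solver step (h).
#' @return A list (class `synthetic_study`) with `cohort`, `observations`
#'   (`patient_id`, `time_h`, `conc_ng_ml`), `scenario` and `spec`.
#' @export
synthetic_study <- function(spec = cohort_spec(), params = ddi_params(),
                            days = 21, dt = 0.05) {
  cohort <- make_cohort(spec)
  scen <- synthetic_scenario(days, spec$sampling_times)
  obs <- lapply(cohort$patient_id, function(id) {
    traj <- simulate_ddi(cohort_patient(cohort, id), scen$riv_regimen,
                         scen$rif_regimen, scen$t_end, dt, params)
    o <- make_observations(traj, scen$sample_times, spec$cv,
                           seed = spec$seed + id)
    cbind(patient_id = id, o)
  })
  structure(list(cohort = cohort, observations = do.call(rbind, obs),
                 scenario = scen, spec = spec),
            class = "synthetic_study")
}

#' Predicted-versus-observed fold-error report
#'
#' Re-simulates the generating scenario for each patient, interpolates
#' predictions at the observation times, and reports per-point fold errors
#' and the fraction below 2 (the conventional acceptance region).
#' Observations outside the simulated horizon are excluded with a warning.
#'
#' @param study A `synthetic_study`, or a list with `cohort`, `observations`
#'   and `scenario` in the same layout (e.g. observations read from CSV).
#' @param params A [ddi_params()] bundle (must match the generating model for
#'   self-validation).
#' @param dt Solver step (h).
#' @return A list (class `validation_report`) with `points` (per-point table
#'   including `fold_error`), `fraction_lt2` and `n`.
#' @export
validation_report <- function(study, params = ddi_params(), dt = 0.05) {
  obs <- study$observations
  scen <- study$scenario
  out_of_span <- obs$time_h > scen$t_end | obs$time_h < 0
  if (any(out_of_span)) {
    warning(sprintf("validation_report: %d observation(s) outside the horizon excluded",
                    sum(out_of_span)))
    obs <- obs[!out_of_span, ]
  }
  pts <- lapply(split(obs, obs$patient_id), function(po) {
    id <- po$patient_id[1L]
    traj <- simulate_ddi(cohort_patient(study$cohort, id), scen$riv_regimen,
                         scen$rif_regimen, scen$t_end, dt, params)
    po$pred_ng_ml <- stats::approx(traj$time, conc_rivaroxaban(traj),
                                   xout = po$time_h)$y
    po$fold_error <- fold_error(po$conc_ng_ml, po$pred_ng_ml)
    po
  })
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  structure(list(points = points,
                 fraction_lt2 = mean(points$fold_error < 2),
                 n = nrow(points)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d points; %.1f%% with fold error < 2 (median %.3f)\n",
    x$n, 100 * x$fraction_lt2, stats::median(x$points$fold_error)))
  invisible(x)
}
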