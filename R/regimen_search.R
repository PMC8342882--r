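#' Default candidate grid for co-medication regimen search
#'
#' @return A data.frame of candidate rivaroxaban regimens (`dose` mg,
#'   `freq` "qd"/"bid"): \{2.5, 5, 10, 15, 20\} mg at qd and bid.
#' @export
default_regimen_grid <- function() {
  expand.grid(dose = c(2.5, 5, 10, 15, 20), freq = c("qd", "bid"),
              stringsAsFactors = FALSE)
}

# steady-state day for regimen acceptance: detected day, capped at `cap`
ss_day_capped <- function(exposure, cap = 21L) {
  ss <- withCallingHandlers(detect_steady_state(exposure),
                            warning = function(w) invokeRestart("muffleWarning"))
  min(ss, cap, nrow(exposure))
}

#' Evaluate candidate rivaroxaban regimens under rifampin co-medication
#'
#' Simulates each candidate from a cold start together with rifampin (600 mg
#' qd by default, first doses at the same clock time) to steady state and
#' reports Cmax/AUC on day 1, day 2 and at steady state. A candidate is
#' accepted iff its steady-state Cmax and daily AUC are inside the window.
#'
#' @param candidates Data.frame with columns `dose` (mg) and `freq`
#'   (`"qd"`/`"bid"`); defaults to [default_regimen_grid()].
#' @param patient A [patient()]; defaults to the reference patient.
#' @param params A [ddi_params()] bundle.
#' @param window An [exposure_window()].
#' @param rif_dose Rifampin dose (mg, once daily).
#' @param horizon_days Simulation horizon in days (>= 22 recommended so the
#'   enzyme turnover approaches steady state; acceptance uses the detected
#'   steady-state day capped at day 21).
#' @param dt Solver step (h).
#' @return A `regimen_recommendation` data.frame: one row per candidate with
#'   `label`, day-1/day-2/steady-state metrics, steady-state day, risk flags
#'   and `accepted`.
#' @export
evaluate_comedication_grid <- function(candidates = default_regimen_grid(),
                                       patient = reference_patient(),
                                       params = ddi_params(),
                                       window = exposure_window(),
                                       rif_dose = 600, horizon_days = 22,
                                       dt = 0.05) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("evaluate_comedication_grid: empty candidate list")
  rif_reg <- regimen_qd(rif_dose, horizon_days)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    dose <- candidates$dose[i]; freq <- candidates$freq[i]
    riv_reg <- regimen_pattern(dose, freq, horizon_days)
    traj <- simulate_ddi(patient, riv_reg, rif_reg, horizon_days * 24, dt,
                         params)
    exp_day <- daily_exposure(traj, window)
    ss <- ss_day_capped(exp_day)
    fl <- classify_exposure(exp_day$cmax[ss], exp_day$auc[ss], window)
    data.frame(label = sprintf("%g mg %s", dose, freq),
               dose = dose, freq = freq,
               cmax_d1 = exp_day$cmax[1], auc_d1 = exp_day$auc[1],
               cmax_d2 = exp_day$cmax[2], auc_d2 = exp_day$auc[2],
               ss_day = ss,
               cmax_ss = exp_day$cmax[ss], auc_ss = exp_day$auc[ss],
               thrombosis_risk = fl$thrombosis_risk,
               bleeding_risk = fl$bleeding_risk,
               accepted = fl$in_window)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regimen_recommendation", "data.frame")
  out
}

#' Choose a reduced day-1 dose when starting co-medication
#'
#' On the first day of co-medication the enzymes are still uninduced, so the
#' steady-state maintenance regimen overshoots the window. This search keeps
#' the maintenance regimen from day 2 on and tries reduced day-1 regimens,
#' returning the largest day-1 candidate (by total daily dose; ties broken
#' toward the higher single dose) for which the day-1, day-2 and steady-state
#' metrics are all inside the window.
#'
#' @param maintenance List with `dose` (mg) and `freq` for days >= 2;
#'   default 15 mg bid.
#' @param day1_candidates Data.frame of day-1 candidates (`dose`, `freq`);
#'   default \{5 qd, 10 qd, 15 qd, 15 bid\}.
#' @inheritParams evaluate_comedication_grid
#' @return A list with `feasible` (logical), the selected `dose`/`freq` (or
#'   `NA` when infeasible), and `table` giving per-candidate metrics.
#' @export
plan_initiation <- function(maintenance = list(dose = 15, freq = "bid"),
                            day1_candidates = data.frame(
                              dose = c(5, 10, 15, 15),
                              freq = c("qd", "qd", "qd", "bid")),
                            patient = reference_patient(),
                            params = ddi_params(),
                            window = exposure_window(),
                            rif_dose = 600, horizon_days = 22, dt = 0.05) {
  if (is.null(day1_candidates) || nrow(day1_candidates) == 0L)
    return(list(feasible = FALSE, dose = NA_real_, freq = NA_character_,
                table = data.frame()))
  rif_reg <- regimen_qd(rif_dose, horizon_days)
  rows <- lapply(seq_len(nrow(day1_candidates)), function(i) {
    d1 <- day1_candidates[i, ]
    riv_reg <- regimen_join(
      regimen_pattern(d1$dose, d1$freq, days = 1),
      regimen_pattern(maintenance$dose, maintenance$freq,
                      days = horizon_days - 1, start = 24))
    traj <- simulate_ddi(patient, riv_reg, rif_reg, horizon_days * 24, dt,
                         params)
    exp_day <- daily_exposure(traj, window)
    ss <- ss_day_capped(exp_day)
    ok <- all(exp_day$in_window[c(1L, 2L, ss)])
    data.frame(dose = d1$dose, freq = d1$freq,
               daily_mg = d1$dose * ifelse(d1$freq == "bid", 2, 1),
               cmax_d1 = exp_day$cmax[1], auc_d1 = exp_day$auc[1],
               cmax_d2 = exp_day$cmax[2], auc_d2 = exp_day$auc[2],
               ss_day = ss, cmax_ss = exp_day$cmax[ss],
               auc_ss = exp_day$auc[ss], feasible = ok)
  })
  tab <- do.call(rbind, rows)
  feas <- which(tab$feasible)
  if (length(feas) == 0L)
    return(list(feasible = FALSE, dose = NA_real_, freq = NA_character_,
                table = tab))
  best <- feas[order(-tab$daily_mg[feas], -tab$dose[feas])][1L]
  list(feasible = TRUE, dose = tab$dose[best], freq = tab$freq[best],
       table = tab)
}

# simulate the co-medication maintenance phase and return the warm state
comedication_warm_state <- function(patient, params,
                                    maintenance = list(dose = 15, freq = "bid"),
                                    rif_dose = 600, comed_days = 21,
                                    dt = 0.05) {
  traj <- simulate_ddi(patient,
                       regimen_pattern(maintenance$dose, maintenance$freq,
                                       comed_days),
                       regimen_qd(rif_dose, comed_days),
                       comed_days * 24, dt, params)
  traj$state[nrow(traj$state), ]
}

# distance of a (cmax, auc) record from the window (0 when inside)
window_miss <- function(cmax, auc, window) {
  max(0, (window$auc_lo - auc) / window$auc_lo) +
    max(0, (auc - window$auc_hi) / window$auc_hi) +
    max(0, (cmax - window$cmax_hi) / window$cmax_hi)
}

#' Plan the rivaroxaban taper after rifampin withdrawal
#'
#' Starting from the co-medication steady state (warm enzyme activities),
#' rifampin is stopped and the enzymes de-induce over about two weeks
#' (washout half-life ~72 h), so a fixed regimen either under- or over-shoots
#' the window. This greedy day-by-day search picks, for each post-withdrawal
#' day, the lowest candidate daily dose whose Cmax and 24-h AUC stay inside
#' the window given the carried-over drug and enzyme state. The two fixed
#' strategies (immediate switch to 10 mg qd; maintained 15 mg bid) are also
#' evaluated for comparison.
#'
#' @param candidates Data.frame of per-day regimen candidates (`dose`,
#'   `freq`); default \{10 qd, 15 qd, 10 bid, 15 bid\}.
#' @param n_days Number of post-withdrawal days to schedule.
#' @param maintenance Co-medication maintenance regimen before withdrawal.
#' @param comed_days Days of co-medication used to establish steady state.
#' @param horizon_fixed Days over which the fixed strategies are followed
#'   (the maintained strategy needs ~2 weeks to show its upper-bound
#'   crossing).
#' @inheritParams evaluate_comedication_grid
#' @return A list with `schedule` (per-day chosen dose and metrics;
#'   infeasible days are flagged with their nearest-miss metrics),
#'   `immediate` and `maintained` per-day metric tables, `crossing_day`
#'   (first day the maintained strategy's AUC exceeds the upper bound, `NA`
#'   if never within `horizon_fixed`), and `warm_state` (the state at
#'   withdrawal).
#' @export
plan_withdrawal <- function(candidates = data.frame(
                              dose = c(10, 15, 10, 15),
                              freq = c("qd", "qd", "bid", "bid")),
                            n_days = 7,
                            patient = reference_patient(),
                            params = ddi_params(),
                            window = exposure_window(),
                            maintenance = list(dose = 15, freq = "bid"),
                            rif_dose = 600, comed_days = 21,
                            horizon_fixed = 16, dt = 0.05) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("plan_withdrawal: empty candidate list")
  y0 <- comedication_warm_state(patient, params, maintenance, rif_dose,
                                comed_days, dt)
  candidates$daily_mg <- candidates$dose *
    ifelse(candidates$freq == "bid", 2, 1)
  ord <- order(candidates$daily_mg, candidates$dose)
  candidates <- candidates[ord, , drop = FALSE]
  no_rif <- regimen()

  state <- y0
  sched <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    chosen <- NULL; chosen_state <- NULL
    best_miss <- Inf; best_row <- NULL; best_state <- NULL
    for (i in seq_len(nrow(candidates))) {
      reg <- regimen_pattern(candidates$dose[i], candidates$freq[i], days = 1)
      traj <- simulate_ddi(patient, reg, no_rif, 24, dt, params,
                           init_state = state)
      m <- interval_metrics(traj, 0, 24)
      fl <- classify_exposure(m[["cmax"]], m[["auc"]], window)
      row <- data.frame(day = day, dose = candidates$dose[i],
                        freq = candidates$freq[i],
                        daily_mg = candidates$daily_mg[i],
                        cmax = m[["cmax"]], auc = m[["auc"]],
                        feasible = fl$in_window)
      if (fl$in_window) {
        chosen <- row
        chosen_state <- traj$state[nrow(traj$state), ]
        break
      }
      miss <- window_miss(m[["cmax"]], m[["auc"]], window)
      if (miss < best_miss) {
        best_miss <- miss; best_row <- row
        best_state <- traj$state[nrow(traj$state), ]
      }
    }
    if (is.null(chosen)) { # infeasible day: carry on with the nearest miss
      chosen <- best_row
      chosen_state <- best_state
    }
    sched[[day]] <- chosen
    state <- chosen_state
  }
  schedule <- do.call(rbind, sched)

  fixed_strategy <- function(dose, freq) {
    traj <- simulate_ddi(patient, regimen_pattern(dose, freq, horizon_fixed),
                         no_rif, horizon_fixed * 24, dt, params,
                         init_state = y0)
    daily_exposure(traj, window)
  }
  immediate <- fixed_strategy(10, "qd")
  maintained <- fixed_strategy(maintenance$dose, maintenance$freq)
  over <- which(maintained$auc > window$auc_hi)
  list(schedule = schedule, immediate = immediate, maintained = maintained,
       crossing_day = if (length(over)) maintained$day[over[1L]] else NA_integer_,
       warm_state = y0)
}
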