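#' Rifampin model right-hand side
#'
#' One-compartment model with first-order absorption and elimination; the
#' elimination clearance is [rifampin_total_clearance()] evaluated at the
#' current hepatic activity, which couples rifampin kinetics to its own
#' induction (autoinduction).
#'
#' @param state Numeric vector `c(A_gut, C_plasma)`: depot amount (mg) and
#'   central concentration (mg/L).
#' @param Et_liver Relative hepatic CYP3A4 activity (fold).
#' @param params A [rifampin_params()] object.
#' @param body_weight Body weight (kg); the apparent volume is
#'   `params$V * body_weight`.
#' @return Derivative vector `c(dA_gut, dC_plasma)` per hour.
#' @export
rifampin_rhs <- function(state, Et_liver, params, body_weight) {
  stopifnot(inherits(params, "rifampin_params"))
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("rifampin_rhs: 'body_weight' must be positive")
  V <- params$V * body_weight
  cl <- rifampin_total_clearance(Et_liver, params)
  c(-params$Ka * state[1L],
    params$Ka * state[1L] / V - cl / V * state[2L])
}

#' Rivaroxaban total clearance under induction and renal function
#'
#' Pathway-partitioned apparent clearance. The CYP3A4 fraction scales with
#' the hepatic activity, the P-gp tubular-secretion fraction with the renal
#' activity, and both renal pathways (P-gp and glomerular filtration) scale
#' linearly with the patient's creatinine clearance relative to the
#' reference:
#' \deqn{CL = CL_{total}\left[f_{CYP} E_{t,liver} + f_{other} +
#'   r \,(f_{Pgp} E_{t,renal} + f_{GFR})\right],\quad r = CrCL/CrCL_{ref}}
#'
#' @param params A [rivaroxaban_params()] object.
#' @param enz An [enzyme_state()] object.
#' @param patient A [patient()] object.
#' @return Clearance in L/h. Equals `params$CL_total` at baseline activities
#'   and reference renal function.
#' @examples
#' p <- rivaroxaban_params()
#' induced_total_clearance(p, enzyme_state(1, 1),
#'                         patient(crcl = p$crcl_ref))
#' @export
induced_total_clearance <- function(params, enz, patient) {
  stopifnot(inherits(params, "rivaroxaban_params"),
            inherits(enz, "enzyme_state"),
            inherits(patient, "patient"))
  r <- patient$crcl / params$crcl_ref
  params$CL_total *
    (induced_cl_cyp(params$f_cyp3a4, enz$Et_liver) + params$f_hep_other +
       r * (induced_cl_pgp(params$f_pgp, enz$Et_renal) + params$f_gfr))
}

#' Rivaroxaban model right-hand side
#'
#' One-compartment disposition with first-order absorption; elimination uses
#' [induced_total_clearance()] at the current enzyme state.
#'
#' @param state Numeric vector `c(A_gut, C_central)`: depot amount (mg) and
#'   central concentration (mg/L; multiply by 1000 for ng/ml).
#' @param enz An [enzyme_state()] object.
#' @param params A [rivaroxaban_params()] object.
#' @param patient A [patient()] object.
#' @return Derivative vector `c(dA_gut, dC_central)` per hour.
#' @export
rivaroxaban_rhs <- function(state, enz, params, patient) {
  stopifnot(inherits(params, "rivaroxaban_params"))
  cl <- induced_total_clearance(params, enz, patient)
  c(-params$Ka_riv * state[1L],
    params$Ka_riv * state[1L] / params$V_riv - cl / params$V_riv * state[2L])
}

#' Closed-form one-compartment oral concentration profile
#'
#' Bateman function for a single oral bolus with first-order absorption and
#' elimination, used as an analytic oracle for the numerical engine:
#' \deqn{C(t) = \frac{D k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})}
#'
#' @param t Time since dose (h).
#' @param dose Dose (mg).
#' @param Ka Absorption rate constant (1/h).
#' @param V Apparent volume (L).
#' @param CL Clearance (L/h); `ke = CL / V`.
#' @return Concentration in mg/L.
#' @export
bateman_concentration <- function(t, dose, Ka, V, CL) {
  ke <- CL / V
  if (abs(Ka - ke) < 1e-12)
    return(dose * Ka * t * exp(-Ka * t) / V)
  dose * Ka / (V * (Ka - ke)) * (exp(-ke * t) - exp(-Ka * t))
}
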