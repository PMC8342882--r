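#' Rate of change of relative enzyme activity under an inducer
#'
#' Enzyme-turnover induction kinetics. Synthesis is stimulated by the unbound
#' inducer concentration at the site through an Emax model whose EC50 is
#' corrected by the hepatocyte-incubation unbound fraction `fu_hep`;
#' degradation is first order with rate `Kdeg`:
#'
#' \deqn{dE_t/dt = K_{deg} E_0 E_{max}
#'   \frac{f_u C}{EC_{50} f_{u,hep} + f_u C} + K_{deg}(E_0 - E_t)}
#'
#' The same equation is applied at the hepatic (CYP3A4) and renal (P-gp)
#' sites with their site-specific unbound fractions.
#'
#' @param Et Current relative activity (fold), > 0.
#' @param C_site Total inducer concentration at the site (uM), >= 0.
#' @param params An [induction_params()] object.
#' @param fu Site-specific unbound fraction of the inducer; defaults to
#'   `params$fu_liver`.
#' @return dEt/dt in fold per hour.
#' @examples
#' p <- induction_params()
#' enzyme_rate(1, 0, p)                       # baseline is a fixed point
#' enzyme_rate(1, 0.336 / p$fu_liver, p)      # half-saturation: Kdeg*Emax/2
#' @export
enzyme_rate <- function(Et, C_site, params, fu = params$fu_liver) {
  stopifnot(inherits(params, "induction_params"))
  if (!is.numeric(Et) || any(Et <= 0))
    stop("enzyme_rate: 'Et' must be positive")
  if (!is.numeric(C_site) || any(C_site < 0))
    stop("enzyme_rate: 'C_site' must be non-negative")
  occ <- (fu * C_site) / (params$EC50 * params$fu_hep + fu * C_site)
  occ[C_site == 0] <- 0 # guard 0/0 when EC50*fu_hep could underflow
  params$Kdeg * params$E0 * params$Emax * occ + params$Kdeg * (params$E0 - Et)
}

#' Steady-state relative activity at constant inducer concentration
#'
#' Closed-form fixed point of [enzyme_rate()]:
#' \eqn{E_{ss} = E_0 (1 + E_{max} \cdot f_u C / (EC_{50} f_{u,hep} + f_u C))}.
#' Bounded by `E0 * (1 + Emax)` (10-fold at the defaults).
#'
#' @inheritParams enzyme_rate
#' @return Steady-state activity (fold).
#' @export
steady_state_activity <- function(C_site, params, fu = params$fu_liver) {
  stopifnot(inherits(params, "induction_params"))
  if (!is.numeric(C_site) || any(C_site < 0))
    stop("steady_state_activity: 'C_site' must be non-negative")
  occ <- (fu * C_site) / (params$EC50 * params$fu_hep + fu * C_site)
  occ[C_site == 0] <- 0
  params$E0 * (1 + params$Emax * occ)
}

#' Induced pathway clearances
#'
#' Linear scaling of the CYP3A4-mediated clearance by the hepatic activity
#' and of the P-gp-mediated tubular secretion clearance by the renal
#' activity.
#'
#' @param cl_cyp,cl_tubular Baseline pathway clearance (L/h), >= 0.
#' @param Et_liver,Et_renal Relative activity (fold), > 0.
#' @return Induced clearance (L/h).
#' @export
induced_cl_cyp <- function(cl_cyp, Et_liver) {
  if (!is.numeric(cl_cyp) || any(cl_cyp < 0))
    stop("induced_cl_cyp: clearance must be non-negative")
  if (any(Et_liver <= 0)) stop("induced_cl_cyp: 'Et_liver' must be positive")
  cl_cyp * Et_liver
}

#' @rdname induced_cl_cyp
#' @export
induced_cl_pgp <- function(cl_tubular, Et_renal) {
  if (!is.numeric(cl_tubular) || any(cl_tubular < 0))
    stop("induced_cl_pgp: clearance must be non-negative")
  if (any(Et_renal <= 0)) stop("induced_cl_pgp: 'Et_renal' must be positive")
  cl_tubular * Et_renal
}

#' Total rifampin clearance with self-induction
#'
#' Decomposes total clearance into the renal part, the CYP3A4-mediated
#' hepatic part (scaled by the hepatic activity) and the remaining hepatic
#' part:
#' \deqn{CL(E_t) = CL_R + f_m E_t (CL_t - CL_R) + (1 - f_m)(CL_t - CL_R)}
#' At baseline (`Et_liver = 1`) this returns `CL_t` exactly.
#'
#' @param Et_liver Relative hepatic CYP3A4 activity (fold).
#' @param rif A [rifampin_params()] object.
#' @return Total clearance (L/h).
#' @examples
#' rifampin_total_clearance(1, rifampin_params())  # 7.4 L/h, uninduced
#' @export
rifampin_total_clearance <- function(Et_liver, rif) {
  stopifnot(inherits(rif, "rifampin_params"))
  if (any(Et_liver <= 0))
    stop("rifampin_total_clearance: 'Et_liver' must be positive")
  hep <- rif$CL_t - rif$CL_R
  rif$CL_R + rif$fm_CYP3A4 * Et_liver * hep + (1 - rif$fm_CYP3A4) * hep
}

#' Inducer concentration at the induction sites
#'
#' The hepatic site concentration is the plasma concentration scaled by the
#' liver partition coefficient; the renal site uses the plasma concentration
#' directly (no renal partition coefficient is available). Both are converted
#' from mg/L to uM via the inducer molar mass. Unbound fractions are applied
#' inside [enzyme_rate()], not here.
#'
#' @param C_plasma Plasma concentration (mg/L), >= 0.
#' @param params An [induction_params()] object.
#' @return Site concentration in uM.
#' @examples
#' liver_site_concentration(0.82294, induction_params()) # 0.27 uM
#' @export
liver_site_concentration <- function(C_plasma, params) {
  stopifnot(inherits(params, "induction_params"))
  if (any(C_plasma < 0))
    stop("liver_site_concentration: 'C_plasma' must be non-negative")
  params$Kp_liver * C_plasma / params$mw_inducer * 1000
}

#' @rdname liver_site_concentration
#' @export
renal_site_concentration <- function(C_plasma, params) {
  stopifnot(inherits(params, "induction_params"))
  if (any(C_plasma < 0))
    stop("renal_site_concentration: 'C_plasma' must be non-negative")
  C_plasma / params$mw_inducer * 1000
}
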