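#' Induction-model parameters
#'
#' Turnover/induction constants for the enzyme-activity model shared by the
#' hepatic CYP3A4 and renal P-gp sites, plus the inducer partitioning terms
#' needed to express site concentrations in micromolar units. Defaults are the
#' literature values for rifampin induction of CYP3A4; P-gp induction is
#' assumed to follow the same kinetics (both are PXR-regulated).
#'
#' @param E0 Baseline relative enzyme activity (fold). 1 by definition in the
#'   absence of induction.
#' @param Emax Maximal induction effect (fold increase over baseline).
#' @param EC50 Inducer concentration producing half-maximal induction (uM),
#'   as measured in hepatocyte incubations.
#' @param Kdeg First-order enzyme degradation rate constant (1/h). Sets both
#'   the onset and washout half-life of induction, `log(2)/Kdeg` (~72 h).
#' @param fu_hep Unbound fraction of inducer in the hepatocyte incubation
#'   (dimensionless); corrects `EC50` to an unbound scale.
#' @param Kp_liver Liver-to-plasma partition coefficient of the inducer.
#' @param fu_liver Unbound fraction of inducer in liver.
#' @param fu_renal_site Unbound fraction of inducer applied at the renal
#'   site. Defaults to `fu_liver` (no renal-specific value is available).
#' @param mw_inducer Molar mass of the inducer (g/mol); bridges mass-based
#'   plasma concentrations (mg/L) to the micromolar `EC50` scale.
#'
#' @return An object of class `induction_params`.
#' @examples
#' p <- induction_params()
#' steady_state_activity(1e6, p) # saturating inducer: E0 * (1 + Emax) = 10
#' @export
induction_params <- function(E0 = 1, Emax = 9, EC50 = 0.8, Kdeg = 0.0096,
                             fu_hep = 0.42, Kp_liver = 0.27, fu_liver = 0.609,
                             fu_renal_site = fu_liver, mw_inducer = 822.94) {
  p <- list(E0 = E0, Emax = Emax, EC50 = EC50, Kdeg = Kdeg, fu_hep = fu_hep,
            Kp_liver = Kp_liver, fu_liver = fu_liver,
            fu_renal_site = fu_renal_site, mw_inducer = mw_inducer)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("induction_params: '", nm, "' must be a positive finite number")
  }
  for (nm in c("fu_hep", "fu_liver", "fu_renal_site")) {
    if (p[[nm]] > 1) stop("induction_params: '", nm, "' must be in (0, 1]")
  }
  structure(p, class = "induction_params")
}

#' Rifampin pharmacokinetic parameters
#'
#' One-compartment apparent oral parameters for the perpetrator drug.
#' Bioavailability is absorbed into `CL_t` and `V` (no explicit F term).
#'
#' @param Ka First-order absorption rate constant (1/h).
#' @param V Apparent volume of distribution per body weight (L/kg).
#' @param CL_t Total clearance of a single (uninduced) dose (L/h).
#' @param CL_R Renal clearance (L/h); not subject to self-induction.
#' @param fm_CYP3A4 Fraction of hepatic intrinsic clearance mediated by
#'   CYP3A4, the self-induced pathway (dimensionless, in \[0, 1\]).
#'
#' @return An object of class `rifampin_params`.
#' @export
rifampin_params <- function(Ka = 0.58, V = 0.33, CL_t = 7.4, CL_R = 1.5,
                            fm_CYP3A4 = 0.2) {
  for (x in list(Ka = Ka, V = V, CL_t = CL_t, CL_R = CL_R)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("rifampin_params: rates, volumes and clearances must be positive")
  }
  if (!is.numeric(fm_CYP3A4) || fm_CYP3A4 < 0 || fm_CYP3A4 > 1)
    stop("rifampin_params: 'fm_CYP3A4' must be in [0, 1]")
  if (CL_R > CL_t)
    stop("rifampin_params: renal clearance 'CL_R' cannot exceed 'CL_t'")
  structure(list(Ka = Ka, V = V, CL_t = CL_t, CL_R = CL_R,
                 fm_CYP3A4 = fm_CYP3A4),
            class = "rifampin_params")
}

#' Rivaroxaban disposition parameters
#'
#' Reduced (one-compartment, first-order absorption) disposition model for the
#' victim drug, with total apparent clearance partitioned into four pathways:
#' hepatic CYP3A4-mediated metabolism, hepatic non-CYP3A4 elimination
#' (hydrolysis and other CYPs), renal P-gp-mediated tubular secretion, and
#' renal glomerular filtration. The CYP3A4 and P-gp pathways scale with the
#' induced enzyme activities; both renal pathways scale linearly with the
#' patient's creatinine clearance relative to `crcl_ref`.
#'
#' Defaults are a calibration (see the methods vignette): uninduced 10 mg qd
#' steady-state exposure sits inside the reference window, and steady-state
#' induced clearance under rifampin 600 mg qd is roughly tripled, so that a
#' tripled daily dose (15 mg bid) restores in-window exposure.
#'
#' @param Ka_riv First-order absorption rate constant (1/h).
#' @param V_riv Apparent central volume (L).
#' @param CL_total Apparent total clearance at baseline (L/h) at reference
#'   renal function.
#' @param f_cyp3a4,f_hep_other,f_pgp,f_gfr Pathway fractions of `CL_total`;
#'   must sum to 1.
#' @param crcl_ref Reference creatinine clearance (ml/min) at which the renal
#'   pathway scalar equals 1.
#'
#' @return An object of class `rivaroxaban_params`.
#' @export
rivaroxaban_params <- function(Ka_riv = 1.4, V_riv = 50, CL_total = 9.3,
                               f_cyp3a4 = 0.35, f_hep_other = 0.21,
                               f_pgp = 0.38, f_gfr = 0.06, crcl_ref = 104) {
  for (x in list(Ka_riv = Ka_riv, V_riv = V_riv, CL_total = CL_total,
                 crcl_ref = crcl_ref)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("rivaroxaban_params: rates, volumes and clearances must be positive")
  }
  f <- c(f_cyp3a4 = f_cyp3a4, f_hep_other = f_hep_other, f_pgp = f_pgp,
         f_gfr = f_gfr)
  if (any(f < 0) || any(f > 1))
    stop("rivaroxaban_params: pathway fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-12)
    stop("rivaroxaban_params: pathway fractions must sum to 1 (got ",
         format(sum(f), digits = 15), ")")
  structure(list(Ka_riv = Ka_riv, V_riv = V_riv, CL_total = CL_total,
                 f_cyp3a4 = f_cyp3a4, f_hep_other = f_hep_other,
                 f_pgp = f_pgp, f_gfr = f_gfr, crcl_ref = crcl_ref),
            class = "rivaroxaban_params")
}

#' Patient covariates
#'
#' @param age Age in years.
#' @param weight Body weight (kg); scales the rifampin volume of distribution.
#' @param sex `"male"` or `"female"` (no covariate effect in the model;
#'   carried for cohort description).
#' @param crcl Creatinine clearance (ml/min); scales the rivaroxaban renal
#'   pathways.
#'
#' @return An object of class `patient`.
#' @examples
#' # Reference patient used for the regimen analyses (Table-style case 1)
#' reference_patient()
#' @export
patient <- function(age = 64, weight = 60.3, sex = c("male", "female"),
                    crcl = 118) {
  sex <- match.arg(sex)
  if (!is.numeric(weight) || weight <= 0) stop("patient: weight must be > 0")
  if (!is.numeric(crcl) || crcl <= 0) stop("patient: crcl must be > 0")
  if (!is.numeric(age) || age <= 0) stop("patient: age must be > 0")
  structure(list(age = age, weight = weight, sex = sex, crcl = crcl),
            class = "patient")
}

#' @rdname patient
#' @export
reference_patient <- function() patient(64, 60.3, "male", 118)

#' Median synthetic patient for calibration-window checks
#'
#' Midpoint of the cohort characteristic ranges (weight 60-67 kg, creatinine
#' clearance 52-129 ml/min rounded to the cohort median of 108).
#' @return A `patient`.
#' @export
median_patient <- function() patient(64, 63.5, "male", 108)

#' Relative enzyme/transporter activity state
#'
#' The dynamic interaction state: relative CYP3A4 activity in liver and
#' relative P-gp activity in kidney, both as fold of baseline.
#'
#' @param Et_liver Relative hepatic CYP3A4 activity (fold).
#' @param Et_renal Relative renal P-gp activity (fold).
#' @return An object of class `enzyme_state`.
#' @export
enzyme_state <- function(Et_liver = 1, Et_renal = 1) {
  if (Et_liver <= 0 || Et_renal <= 0)
    stop("enzyme_state: activities must be positive")
  structure(list(Et_liver = Et_liver, Et_renal = Et_renal),
            class = "enzyme_state")
}

#' Bundle of all drug-model parameters
#'
#' @param induction An [induction_params()] object.
#' @param rifampin A [rifampin_params()] object.
#' @param rivaroxaban A [rivaroxaban_params()] object.
#' @return An object of class `ddi_params`.
#' @export
ddi_params <- function(induction = induction_params(),
                       rifampin = rifampin_params(),
                       rivaroxaban = rivaroxaban_params()) {
  stopifnot(inherits(induction, "induction_params"),
            inherits(rifampin, "rifampin_params"),
            inherits(rivaroxaban, "rivaroxaban_params"))
  structure(list(induction = induction, rifampin = rifampin,
                 rivaroxaban = rivaroxaban),
            class = "ddi_params")
}

#' @export
print.patient <- function(x, ...) {
  cat(sprintf("<patient> %s, %g y, %g kg, CrCL %g ml/min\n",
              x$sex, x$age, x$weight, x$crcl))
  invisible(x)
}

#' @export
print.ddi_params <- function(x, ...) {
  cat("<ddi_params>\n")
  cat(sprintf("  induction:   Emax %g, EC50 %g uM, Kdeg %g /h\n",
              x$induction$Emax, x$induction$EC50, x$induction$Kdeg))
  cat(sprintf("  rifampin:    Ka %g /h, V %g L/kg, CL_t %g L/h (CL_R %g, fm %g)\n",
              x$rifampin$Ka, x$rifampin$V, x$rifampin$CL_t,
              x$rifampin$CL_R, x$rifampin$fm_CYP3A4))
  cat(sprintf("  rivaroxaban: Ka %g /h, V %g L, CL %g L/h, fractions %g/%g/%g/%g\n",
              x$rivaroxaban$Ka_riv, x$rivaroxaban$V_riv,
              x$rivaroxaban$CL_total, x$rivaroxaban$f_cyp3a4,
              x$rivaroxaban$f_hep_other, x$rivaroxaban$f_pgp,
              x$rivaroxaban$f_gfr))
  invisible(x)
}
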