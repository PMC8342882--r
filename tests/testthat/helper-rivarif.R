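# Build a bare trajectory object from an explicit rivaroxaban concentration
# series (ng/ml), for exposure-metric tests with known closed-form answers.
manual_trajectory <- function(time, conc_ng_ml) {
  state <- matrix(0, length(time), 6,
                  dimnames = list(NULL, ddi_state_names()))
  state[, "riv_central"] <- conc_ng_ml / 1000
  structure(list(time = time, state = state, dt = diff(time)[1],
                 patient = reference_patient(), params = ddi_params(),
                 riv_regimen = regimen(), rif_regimen = regimen(),
                 induction = FALSE),
            class = "ddi_trajectory")
}

# Exposure summary from explicit per-day AUCs (for steady-state detection).
manual_summary <- function(auc) {
  data.frame(day = seq_along(auc), cmax = auc / 10, auc = auc)
}

# A rivaroxaban parameter set with round numbers used by several
# arithmetic oracles (clearance composition, dose/CL AUC identities).
round_riv_params <- function() {
  rivaroxaban_params(Ka_riv = 1.4, V_riv = 50, CL_total = 10,
                     f_cyp3a4 = 0.18, f_hep_other = 0.46, f_pgp = 0.30,
                     f_gfr = 0.06, crcl_ref = 104)
}
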