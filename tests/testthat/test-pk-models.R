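test_that("site concentrations convert mass to molar units", {
  p <- induction_params()
  expect_identical(liver_site_concentration(0, p), 0)
  expect_equal(liver_site_concentration(0.82294, p), 0.27, tolerance = 1e-10)
  expect_equal(liver_site_concentration(10, p), 2.7 / 822.94 * 1000,
               tolerance = 1e-10)
  # renal site sees the unpartitioned plasma concentration
  expect_equal(renal_site_concentration(0.82294, p), 1, tolerance = 1e-10)
})

test_that("rifampin rhs reduces to a one-compartment oral model", {
  rif <- rifampin_params()
  expect_identical(rifampin_rhs(c(0, 0), 1, rif, 60), c(0, 0))
  expect_error(rifampin_rhs(c(0, 0), 1, rif, -1), "positive")
  # elimination half-life at baseline activity, 60 kg
  ke <- rifampin_total_clearance(1, rif) / (rif$V * 60)
  expect_equal(log(2) / ke, 1.855, tolerance = 1e-3)
})

test_that("single rifampin dose matches the Bateman closed form", {
  pat <- patient(weight = 60, crcl = 104)
  traj <- simulate_ddi(pat, regimen(), regimen(time = 0, amount = 600),
                       t_end = 48, dt = 0.05, induction = FALSE)
  rif <- rifampin_params()
  exact <- bateman_concentration(traj$time, 600, rif$Ka, rif$V * 60, rif$CL_t)
  expect_lt(max(abs(conc_rifampin(traj) - exact)) / max(exact), 1e-3)
})

test_that("repeated rifampin dosing shows decreasing daily exposure", {
  traj <- simulate_ddi(reference_patient(), regimen(),
                       regimen_qd(600, 12), t_end = 12 * 24, dt = 0.1)
  auc <- vapply(1:12, function(d)
    interval_metrics(traj, (d - 1) * 24, d * 24, drug = "rifampin")[["auc"]],
    numeric(1))
  expect_true(all(diff(auc) <= 1e-9))
  expect_lt(auc[12], 0.85 * auc[1]) # self-induction is substantial
  # and the day-to-day decrease converges
  expect_lt(abs(auc[12] - auc[11]) / auc[11], 0.02)
})

test_that("without a CYP3A4 fraction rifampin kinetics are dose-linear", {
  params <- ddi_params(rifampin = rifampin_params(fm_CYP3A4 = 0))
  pat <- reference_patient()
  multi <- simulate_ddi(pat, regimen(), regimen_qd(600, 3), 96, 0.1,
                        params = params)
  # superpose three single-dose runs with matching horizons
  single <- lapply(c(0, 24, 48), function(t0)
    simulate_ddi(pat, regimen(), regimen(time = t0, amount = 600), 96, 0.1,
                 params = params))
  sup <- Reduce(`+`, lapply(single, conc_rifampin))
  expect_lt(max(abs(conc_rifampin(multi) - sup)) / max(sup), 1e-9)
})

test_that("rivaroxaban clearance composes pathway fractions", {
  p <- round_riv_params()
  base <- patient(crcl = 104)
  expect_equal(induced_total_clearance(p, enzyme_state(1, 1), base), 10,
               tolerance = 1e-12)
  expect_equal(induced_total_clearance(p, enzyme_state(6, 6), base), 34,
               tolerance = 1e-12)
  expect_equal(induced_total_clearance(p, enzyme_state(1, 1),
                                       patient(crcl = 52)),
               10 * (0.18 + 0.46 + 0.5 * 0.36), tolerance = 1e-12)
  expect_error(rivaroxaban_params(f_cyp3a4 = 0.5, f_hep_other = 0.5,
                                  f_pgp = 0.5, f_gfr = 0.5), "sum to 1")
})

test_that("single rivaroxaban dose matches the Bateman form and dose/CL AUC", {
  params <- ddi_params(rivaroxaban = round_riv_params())
  pat <- patient(crcl = 104)
  traj <- simulate_ddi(pat, regimen(time = 0, amount = 10), regimen(),
                       t_end = 120, dt = 0.05, params = params,
                       induction = FALSE)
  conc <- conc_rivaroxaban(traj)
  exact <- 1000 * bateman_concentration(traj$time, 10, 1.4, 50, 10)
  expect_lt(max(abs(conc - exact)) / max(exact), 1e-3)
  auc_inf <- interval_metrics(traj, 0, 120)[["auc"]]
  expect_equal(auc_inf, 1000, tolerance = 1e-3) # 10 mg / 10 L/h, in ng.h/ml
})

test_that("dose proportionality holds at fixed enzyme state", {
  pat <- reference_patient()
  a <- simulate_ddi(pat, regimen_qd(10, 3), regimen(), 72, 0.1,
                    induction = FALSE)
  b <- simulate_ddi(pat, regimen_qd(20, 3), regimen(), 72, 0.1,
                    induction = FALSE)
  expect_equal(2 * conc_rivaroxaban(a), conc_rivaroxaban(b),
               tolerance = 1e-12)
})

test_that("higher enzyme activity strictly lowers rivaroxaban exposure", {
  pat <- reference_patient()
  aucs <- vapply(c(1, 2, 4, 8), function(et) {
    traj <- simulate_ddi(pat, regimen_qd(10, 3), regimen(), 72, 0.1,
                         init_state = c(0, 0, 0, 0, et, et),
                         induction = FALSE)
    interval_metrics(traj, 0, 72)[["auc"]]
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("engine right-hand side agrees with the exported model functions", {
  params <- ddi_params()
  pat <- reference_patient()
  sys <- rivarif:::ddi_system(pat, params, induction = TRUE)
  set.seed(42)
  for (i in 1:25) {
    y <- c(runif(1, 0, 600), runif(1, 0, 15), runif(1, 0, 20),
           runif(1, 0, 0.3), runif(1, 1, 10), runif(1, 1, 10))
    enz <- enzyme_state(y[5], y[6])
    expected <- c(
      rifampin_rhs(y[1:2], y[5], params$rifampin, pat$weight),
      rivaroxaban_rhs(y[3:4], enz, params$rivaroxaban, pat),
      enzyme_rate(y[5], liver_site_concentration(y[2], params$induction),
                  params$induction, fu = params$induction$fu_liver),
      enzyme_rate(y[6], renal_site_concentration(y[2], params$induction),
                  params$induction, fu = params$induction$fu_renal_site))
    expect_equal(sys(0, y), expected, tolerance = 1e-12)
  }
})
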