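test_that("baseline and saturation are fixed points of the turnover model", {
  p <- induction_params()
  expect_identical(enzyme_rate(1, 0, p), 0)
  # at the saturated activity E0*(1+Emax) = 10 the rate vanishes as C -> Inf
  expect_equal(enzyme_rate(10, 1e12, p), 0, tolerance = 1e-9)
})

test_that("enzyme rate at half-saturation matches direct substitution", {
  p <- induction_params()
  # unbound site concentration equal to EC50*fu_hep = 0.336 uM
  C_half <- 0.336 / p$fu_liver
  expect_equal(enzyme_rate(1, C_half, p), 0.0096 * 1 * 9 / 2,
               tolerance = 1e-12)
})

test_that("steady-state activity has the closed Emax form", {
  p <- induction_params()
  expect_identical(steady_state_activity(0, p), 1)
  expect_equal(steady_state_activity(1e12, p), 10, tolerance = 1e-6)
  expect_equal(steady_state_activity(0.336 / p$fu_liver, p), 5.5,
               tolerance = 1e-12)
  # the rate evaluated at the fixed point is zero to machine precision
  for (C in c(0.01, 0.3, 1, 5, 50)) {
    expect_equal(enzyme_rate(steady_state_activity(C, p), C, p), 0,
                 tolerance = 1e-15)
  }
})

test_that("induced pathway clearances scale linearly", {
  expect_identical(induced_cl_cyp(2, 3), 6)
  expect_identical(induced_cl_cyp(1.7, 1), 1.7)
  expect_identical(induced_cl_cyp(0, 5), 0)
  expect_identical(induced_cl_pgp(1, 6), 6)
  expect_identical(induced_cl_pgp(0.5, 2), 1)
  expect_error(induced_cl_cyp(-1, 2), "non-negative")
  expect_error(induced_cl_pgp(1, 0), "positive")
})

test_that("rifampin total clearance follows the induced decomposition", {
  rif <- rifampin_params()
  expect_equal(rifampin_total_clearance(1, rif), 7.4, tolerance = 1e-12)
  expect_equal(rifampin_total_clearance(6, rif), 1.5 + 0.2 * 6 * 5.9 + 0.8 * 5.9,
               tolerance = 1e-12)
  expect_equal(rifampin_total_clearance(10, rif), 18.02, tolerance = 1e-12)
  # affine and strictly increasing in Et when fm > 0
  et <- seq(1, 10, by = 0.5)
  cl <- rifampin_total_clearance(et, rif)
  expect_true(all(diff(cl) > 0))
  expect_equal(diff(cl), rep(diff(cl)[1], length(cl) - 1), tolerance = 1e-12)
  expect_error(rifampin_params(CL_R = 8, CL_t = 7.4), "cannot exceed")
})

test_that("activity relaxes to the analytic exponential at constant inducer", {
  p <- induction_params()
  for (C in c(0.2, 1, 4)) {
    ess <- steady_state_activity(C, p)
    out <- rk4_integrate(function(t, y) enzyme_rate(y, C, p), y0 = 1,
                         t_end = 300, dt = 0.05)
    analytic <- ess - (ess - 1) * exp(-p$Kdeg * out$time)
    expect_lt(max(abs(out$state[, 1] - analytic) / analytic), 1e-9)
    # approach is monotone non-decreasing from baseline
    expect_true(all(diff(out$state[, 1]) >= -1e-12))
  }
})

test_that("washout decays to baseline with the Kdeg half-life", {
  p <- induction_params()
  t_half <- log(2) / p$Kdeg
  expect_equal(t_half, 72.2, tolerance = 1e-3)
  ess <- steady_state_activity(2, p)
  out <- rk4_integrate(function(t, y) enzyme_rate(y, 0, p), y0 = ess,
                       t_end = 400, dt = 0.05)
  analytic <- 1 + (ess - 1) * exp(-p$Kdeg * out$time)
  expect_lt(max(abs(out$state[, 1] - analytic) / analytic), 1e-9)
  # half the induction is gone at t_half (nearest grid point)
  i <- which.min(abs(out$time - t_half))
  expect_equal(out$state[i, 1] - 1, (ess - 1) / 2, tolerance = 1e-4)
})

test_that("activities stay within [E0, E0*(1+Emax)] along dosed trajectories", {
  traj <- simulate_ddi(reference_patient(), regimen(),
                       regimen_qd(600, 10), t_end = 15 * 24, dt = 0.1)
  for (s in c("Et_liver", "Et_renal")) {
    expect_true(all(traj$state[, s] >= 1 - 1e-12))
    expect_true(all(traj$state[, s] <= 10 + 1e-12))
  }
})

test_that("invalid inputs are rejected", {
  p <- induction_params()
  expect_error(enzyme_rate(0, 1, p), "positive")
  expect_error(enzyme_rate(1, -1, p), "non-negative")
  expect_error(steady_state_activity(-1, p), "non-negative")
  expect_error(induction_params(EC50 = -1), "positive")
  expect_error(induction_params(fu_hep = 1.2), "in \\(0, 1\\]")
})
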