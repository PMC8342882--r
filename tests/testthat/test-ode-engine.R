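test_that("RK4 integrates exponential decay to closed-form accuracy", {
  out <- rk4_integrate(function(t, y) -y, 1, t_end = 1, dt = 0.05)
  expect_equal(out$state[nrow(out$state), 1], exp(-1), tolerance = 1e-6)
})

test_that("zero initial state with no doses stays identically zero", {
  traj <- simulate_ddi(reference_patient(), regimen(), regimen(),
                       t_end = 24, dt = 0.1)
  expect_true(all(traj$state[, 1:4] == 0))
  expect_true(all(traj$state[, 5:6] == 1))
})

test_that("global error shrinks ~16x per step halving (order 4)", {
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    out <- rk4_integrate(function(t, y) -y, 1, t_end = 2, dt = dt)
    abs(out$state[nrow(out$state), 1] - exp(-2))
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("dose events superpose for the linear (frozen-induction) system", {
  pat <- reference_patient()
  a <- simulate_ddi(pat, regimen(time = 0, amount = 10), regimen(), 96, 0.05,
                    induction = FALSE)
  b <- simulate_ddi(pat, regimen(time = 24, amount = 5), regimen(), 96, 0.05,
                    induction = FALSE)
  both <- simulate_ddi(pat, regimen(time = c(0, 24), amount = c(10, 5)),
                       regimen(), 96, 0.05, induction = FALSE)
  sum_ab <- conc_rivaroxaban(a) + conc_rivaroxaban(b)
  expect_lt(max(abs(conc_rivaroxaban(both) - sum_ab)) / max(sum_ab), 1e-9)
})

test_that("same-time events are order-independent and summed", {
  pat <- reference_patient()
  a <- simulate_ddi(pat, regimen(time = c(0, 0), amount = c(10, 5)),
                    regimen(), 24, 0.1)
  b <- simulate_ddi(pat, regimen(time = c(0, 0), amount = c(5, 10)),
                    regimen(), 24, 0.1)
  d <- simulate_ddi(pat, regimen(time = 0, amount = 15), regimen(), 24, 0.1)
  expect_identical(a$state, b$state)
  expect_equal(a$state, d$state, tolerance = 1e-14)
})

test_that("off-grid dose times are snapped with a warning", {
  pat <- reference_patient()
  expect_warning(
    simulate_ddi(pat, regimen(time = 0.051, amount = 10), regimen(), 24, 0.1),
    "snapped")
  # an exactly representable grid time does not warn
  expect_no_warning(
    simulate_ddi(pat, regimen(time = 0.1, amount = 10), regimen(), 24, 0.1))
})

test_that("degenerate steps and late doses are rejected", {
  pat <- reference_patient()
  expect_error(rk4_integrate(function(t, y) -y, 1, t_end = 1, dt = 0),
               "positive")
  expect_error(
    simulate_ddi(pat, regimen(time = 24, amount = 10), regimen(), 24, 0.1),
    "beyond 't_end'")
})

test_that("integration failure names the first bad time", {
  expect_error(rk4_integrate(function(t, y) y^2, 10, t_end = 2, dt = 0.1),
               "integration failure at t = ")
})

test_that("halving the default step changes concentrations by far below 0.1%", {
  pat <- reference_patient()
  d <- halve_step_check(pat, regimen_qd(10, 5), regimen_qd(600, 5),
                        t_end = 120, dt = 0.05)
  expect_lt(d, 1e-3)
})

test_that("trajectory agrees with an adaptive-solver reference", {
  skip_if_not_installed("deSolve")
  pat <- reference_patient()
  params <- ddi_params()
  traj <- simulate_ddi(pat, regimen_qd(10, 4), regimen_qd(600, 4),
                       t_end = 96, dt = 0.05, params = params)
  sys <- rivarif:::ddi_system(pat, params, TRUE)
  nm <- ddi_state_names()
  ref <- deSolve::ode(
    y = stats::setNames(c(0, 0, 0, 0, 1, 1), nm),
    times = seq(0, 96, by = 0.05),
    func = function(t, y, p) list(sys(t, y)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12,
    events = list(data = data.frame(
      var = rep(c(nm[1], nm[3]), 4),
      time = rep(c(0, 24, 48, 72), each = 2),
      value = rep(c(600, 10), 4),
      method = "add")))
  riv_ref <- ref[, 5] * 1000
  expect_lt(max(abs(conc_rivaroxaban(traj) - riv_ref)) / max(riv_ref), 2e-3)
})
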