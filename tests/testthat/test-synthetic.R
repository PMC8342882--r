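test_that("cohort generation is seed-deterministic and range-respecting", {
  spec <- cohort_spec()
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(a, b)
  expect_identical(nrow(a), 6L)
  expect_true(all(a$age >= 36 & a$age <= 71))
  expect_true(all(a$weight >= 60 & a$weight <= 67))
  expect_true(all(a$crcl >= 52 & a$crcl <= 129))
  expect_identical(sum(a$sex == "male"), 3L)
  # a different seed gives a different cohort
  expect_false(identical(a$crcl, make_cohort(cohort_spec(seed = 99))$crcl))
  # the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_cohort(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate ranges yield constant covariates", {
  spec <- cohort_spec(weight_range = c(60, 60))
  expect_true(all(make_cohort(spec)$weight == 60))
  expect_error(cohort_spec(n_patients = 0), ">= 1")
  expect_error(cohort_spec(crcl_range = c(120, 50)), "lo <= hi")
})

test_that("observations reduce to model predictions as cv -> 0", {
  traj <- simulate_ddi(reference_patient(), regimen_qd(10, 2), regimen(),
                       48, 0.1)
  times <- c(2, 4, 8, 12, 24)
  obs <- make_observations(traj, times, cv = 0, seed = 5)
  pred <- approx(traj$time, conc_rivaroxaban(traj), xout = times)$y
  expect_equal(obs$conc_ng_ml, pred, tolerance = 1e-12)
  # fixed seed reproduces the draw; different seed does not
  o1 <- make_observations(traj, times, cv = 0.2, seed = 5)
  o2 <- make_observations(traj, times, cv = 0.2, seed = 5)
  o3 <- make_observations(traj, times, cv = 0.2, seed = 6)
  expect_identical(o1, o2)
  expect_false(identical(o1$conc_ng_ml, o3$conc_ng_ml))
})

test_that("sampling at zero model concentration is skipped with a warning", {
  traj <- simulate_ddi(reference_patient(), regimen(time = 24, amount = 10),
                       regimen(), 48, 0.1)
  expect_warning(obs <- make_observations(traj, c(0, 30), cv = 0, seed = 1),
                 "skipped")
  expect_identical(obs$time_h, 30)
  expect_error(make_observations(traj, 100, cv = 0, seed = 1), "outside")
})

test_that("the lognormal residual reproduces the nominal CV", {
  traj <- simulate_ddi(reference_patient(), regimen_qd(10, 2), regimen(),
                       48, 0.1)
  obs <- make_observations(traj, rep(24, 10000), cv = 0.2, seed = 11)
  ratio <- obs$conc_ng_ml / approx(traj$time, conc_rivaroxaban(traj), 24)$y
  emp_cv <- sd(ratio) / mean(ratio)
  expect_lt(abs(emp_cv - 0.2) / 0.2, 0.05)
})

test_that("self-validation of a noise-free study gives unit fold errors", {
  spec <- cohort_spec(n_patients = 2, cv = 0)
  study <- synthetic_study(spec, days = 8, dt = 0.1)
  rep <- validation_report(study, dt = 0.1)
  expect_true(all(abs(rep$points$fold_error - 1) < 1e-9))
  expect_identical(rep$fraction_lt2, 1)
})

test_that("uniformly doubled observations give exactly two-fold errors", {
  spec <- cohort_spec(n_patients = 2, cv = 0)
  study <- synthetic_study(spec, days = 8, dt = 0.1)
  study$observations$conc_ng_ml <- 2 * study$observations$conc_ng_ml
  rep <- validation_report(study, dt = 0.1)
  expect_equal(rep$points$fold_error, rep(2, rep$n), tolerance = 1e-9)
})

test_that("observations beyond the horizon are excluded with a warning", {
  spec <- cohort_spec(n_patients = 1, cv = 0)
  study <- synthetic_study(spec, days = 8, dt = 0.1)
  study$observations <- rbind(study$observations,
                              data.frame(patient_id = 1, time_h = 1e4,
                                         conc_ng_ml = 50))
  expect_warning(rep <- validation_report(study, dt = 0.1), "excluded")
  expect_true(all(rep$points$time_h <= study$scenario$t_end))
})
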