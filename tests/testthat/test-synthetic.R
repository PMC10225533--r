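test_that("cohort generation is a pure function of the configuration", {
  cfg <- simulation_config(seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and differs under another seed
  c <- simulate_cohort(simulation_config(seed = 78))
  expect_false(identical(a$active_responses, c$active_responses))
})

test_that("generated tables satisfy the session-record invariants", {
  s <- simulate_cohort(simulation_config(seed = 5))
  expect_silent(validate_sessions(s))
  expect_true(all(s$infusions <= s$active_responses))
  expect_true(all(s$fr_value[s$phase == "FR1_acq"] == 1))
  expect_true(all(s$fr_value[s$phase == "FR2_acq"] == 2))
  # every subject has the configured 14 acquisition sessions
  acq <- s[s$phase != "demand", ]
  expect_true(all(table(acq$subject_id) == 14))
})

test_that("zero-noise demand phase is the deterministic rounding of the model", {
  q0 <- 1.85; a <- 0.000362; k <- 2.218; dose <- 0.03
  sim <- simulate_demand_phase(q0, a, k, dose_mg_kg = dose)
  # independent recomputation
  expected <- round(10^(log10(q0) + k * (exp(-a * q0 * sim$fr_value / dose)
                                         - 1)) / dose)
  expect_equal(sim$infusions, expected)
  expect_equal(sim$infusions[1],
               round(10^predict_log_consumption(q0, a, k, 100) / dose))
  expect_equal(sim$infusions[nrow(sim)], 0)
  expect_true(all(sim$infusions[-nrow(sim)] > 0))

  # doubling alpha cannot extend the series (monotonicity in alpha)
  sim2 <- simulate_demand_phase(q0, 2 * a, k, dose_mg_kg = dose)
  expect_lte(max(sim2$fr_value), max(sim$fr_value))

  # a too-short ladder errors with advice
  expect_error(simulate_demand_phase(q0, a, k, dose, fr_ladder = c(3, 6, 9)),
               "ladder")
})

test_that("count model obeys the law of large numbers in the Poisson limit", {
  groups <- data.frame(strain = "Wistar", unit_dose_ug_kg = 30,
                       n_male = 100, n_female = 100, acquisition_prob = 1)
  cfg <- simulation_config(seed = 31, groups = groups,
                           count_dispersion = Inf,
                           responder_active_mean = 60)
  s <- simulate_acquisition_cohort(cfg)
  expect_equal(mean(s$active_responses), 60, tolerance = 0.05)
  expect_equal(mean(s$inactive_responses), cfg$inactive_mean,
               tolerance = 0.05)
})

test_that("a drug-free group with acquisition_prob 0 rarely passes", {
  groups <- data.frame(strain = "Wistar", unit_dose_ug_kg = c(4, 0),
                       n_male = c(25, 4), n_female = c(25, 4),
                       acquisition_prob = 0)
  cfg <- simulation_config(seed = 19, groups = groups)
  acq <- classify_cohort(simulate_acquisition_cohort(cfg))
  expect_equal(nrow(acq), 50)
  expect_lt(mean(acq$acquired), 0.2)
})

test_that("fixture cohort is stable and covers all strata", {
  f1 <- make_fixture_cohort()
  f2 <- make_fixture_cohort()
  expect_identical(f1, f2)
  meta <- unique(f1[, c("subject_id", "strain", "unit_dose_ug_kg")])
  expect_equal(nrow(meta), 12)
  expect_setequal(unique(meta$unit_dose_ug_kg), c(30, 4, 0))
  for (st in c("Wistar", "SHR"))
    expect_gte(sum(meta$strain == st & meta$unit_dose_ug_kg == 0), 1)
  expect_silent(validate_sessions(f1))
})

test_that("zero-noise simulation with rounding disabled refits exactly", {
  q0 <- 1.45; a <- 0.00062; k <- 2.218
  sim <- simulate_demand_phase(q0, a, k, dose_mg_kg = 0.03,
                               round_infusions = FALSE)
  ds <- prepare_demand_series(sim[sim$infusions * 0.03 > 0.005, ], 0.03)
  fit <- fit_demand(ds, k = k)
  expect_equal(coef(fit)[["q0"]], q0, tolerance = 1e-6)
  expect_equal(coef(fit)[["alpha"]], a, tolerance = 1e-6)
})
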