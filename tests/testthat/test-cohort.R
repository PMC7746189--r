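degenerate_spec <- function(n = 3)
  cohort_spec(n_patients = n, cv = 0, frac_sd = 0, flux_sigma = 0,
              demo_sds = c(age = 0, bmi = 0, hba1c = 0, duration = 0),
              seed = 11)

test_that("zero dispersion collapses every patient onto the template", {
  co <- sample_cohort(degenerate_spec())
  tpl <- cohort_template()
  p1 <- co$patients[[1]]
  for (f in c("pi", "pm", "ke", "St", "w", "V", "age", "bmi"))
    expect_equal(p1[[f]], tpl[[f]][1])
  expect_equal(flux_at(p1$Im, c(0, 333, 1200)), rep(1, 3))
  strip_id <- function(p) { p$id <- NULL; p }
  expect_identical(strip_id(co$patients[[2]]), strip_id(p1))
  expect_identical(strip_id(co$patients[[3]]), strip_id(p1))
})

test_that("the same spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_patients = 5, seed = 99)
  expect_identical(sample_cohort(spec), sample_cohort(spec))
})

test_that("the canonical cohort has 15 valid patients", {
  co <- fixture_cohort()
  expect_length(co$patients, 15)
  for (p in co$patients) expect_silent(validate_patient(p))
})

test_that("fasting glucose settles in 4-12 mmol/L under basal insulin", {
  # the generator's behavioural validation: every fixture patient held on
  # their own titrated basal stays in a physiological fasting band
  co <- fixture_cohort()
  for (p in co$patients[1:5]) {
    s0 <- init_state(p, trial_protocol(start_glucose = p$G_target))
    s <- integrate_model(s0, p,
                         exogenous_inputs(ui = p$basal_rate,
                                          clock_offset = 480),
                         0, 1440)
    expect_gt(s[["Q1"]] / p$V, 4)
    expect_lt(s[["Q1"]] / p$V, 12)
  }
})

test_that("sampled parameter dispersion matches the spec CV", {
  spec <- cohort_spec(n_patients = 2000, cv = 0.15, seed = 5,
                      flux_knots = 2)
  kes <- local({
    co <- sample_cohort(spec)
    vapply(co$patients, `[[`, numeric(1), "ke")
  })
  cv_hat <- sd(kes) / mean(kes)
  se <- 0.15 * sqrt((1 + 2 * 0.15^2) / (2 * 2000))
  expect_lt(abs(cv_hat - 0.15), 3 * se)
})

test_that("multiplicative fluxes are positive by construction", {
  spec <- cohort_spec(n_patients = 10, flux_sigma = 0.5, seed = 3)
  co <- sample_cohort(spec)
  for (p in co$patients) {
    expect_true(all(flux_at(p$Im, seq(0, 1439)) > 0))
    expect_true(all(flux_at(p$fm, seq(0, 1439)) > 0))
  }
})

test_that("baseline characteristics summarize the five demographics", {
  co <- fixture_cohort()
  tab <- baseline_characteristics(co)
  expect_setequal(tab$characteristic,
                  c("Age (yr)", "BMI (kg/m2)", "HbA1c (%)",
                    "Daily insulin dose (U/kg/day)",
                    "Duration of diabetes (yr)"))
  one <- baseline_characteristics(co$patients[1])
  expect_equal(one$mean, one$median)
  expect_equal(one$sd, rep(0, 5))
  two <- baseline_characteristics(list(
    patient_parameters(id = "a", age = 40),
    patient_parameters(id = "b", age = 54)))
  expect_equal(two$mean[two$characteristic == "Age (yr)"], 47)
  expect_error(baseline_characteristics(list()), "empty")
})
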