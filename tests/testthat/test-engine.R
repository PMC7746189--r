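no_meals <- function(...) {
  trial_protocol(duration_days = 0, duration_hours = 3,
                 meals = meal_plan(name = character(0),
                                   time_min = numeric(0),
                                   cho_g = numeric(0)), ...)
}

zero_controller_factory <- function(patient, protocol)
  controller(init = function(setup) NULL,
             step = function(gs, meal_cho, t)
               list(insulin = 0, glucagon = 0))

test_that("initial state honors the protocol and basal steady state", {
  p <- patient_parameters(ci = 0)
  pr <- trial_protocol(start_glucose = 7, start_glucose_sd = 0)
  s <- init_state(p, pr)
  expect_equal(unname(s[["Gs"]]), 7)
  expect_equal(unname(s[["Q1"]]) / p$V, 7)
  # preloaded at the titrated basal: Qi = (u + ci)/ke
  expect_equal(unname(s[["Qi"]]), (p$basal_rate + p$ci) / p$ke)
  # zero insulin on board empties every insulin compartment
  s0 <- init_state(p, trial_protocol(insulin_on_board = 0))
  expect_equal(max(abs(s0[1:8])), 0)
  # a positive IOB preloads the depot to exactly that mass
  iob <- 1.5
  si <- init_state(p, trial_protocol(insulin_on_board = iob))
  expect_equal(sum(si[1:4]), iob)
})

test_that("the engine reproduces a bare integration under zero dosing", {
  p <- linear_patient(id = "vp01")
  pr <- no_meals(start_glucose = 10, arm = "single-hormone", seed = 4)
  res <- run_trial(list(p), pr, zero_controller_factory)
  run <- res$runs[[1]]
  expect_equal(run$status, "completed")
  direct <- integrate_model(
    init_state(p, pr), p,
    exogenous_inputs(clock_offset = pr$start_clock), 0, 180,
    times = seq(0, 180, 10))
  expect_equal(unname(run$Gs), direct$Gs, tolerance = 1e-7)
  expect_equal(unname(run$G), direct$G, tolerance = 1e-7)
})

test_that("a controller exception fails only that patient", {
  co <- sample_cohort(cohort_spec(n_patients = 3, seed = 8))
  factory <- function(patient, protocol) {
    n <- 0
    controller(init = function(setup) NULL,
               step = function(gs, meal_cho, t) {
                 n <<- n + 1
                 if (patient$id == "vp02" && n == 3) stop("boom")
                 list(insulin = 0, glucagon = 0)
               })
  }
  res <- run_trial(co, no_meals(seed = 5), factory)
  st <- res$report$statuses
  expect_equal(unname(st[c("vp01", "vp03")]), rep("completed", 2))
  expect_match(st[["vp02"]], "controller-failed at t=20.*boom")
  expect_true(anyNA(res$runs[[2]]$Gs))
  expect_false(anyNA(res$runs[[1]]$Gs))
})

test_that("negative or non-finite doses fail the run descriptively", {
  p <- linear_patient(id = "vp01")
  bad <- function(patient, protocol)
    controller(init = function(setup) NULL,
               step = function(gs, meal_cho, t)
                 list(insulin = -1, glucagon = 0))
  res <- run_trial(list(p), no_meals(seed = 5), bad)
  expect_match(res$runs[[1]]$status, "invalid dose")
})

test_that("rescue carbohydrates respect the threshold and lockout", {
  seen_meals <- new.env()
  seen_meals$cho <- numeric()
  watching <- function(patient, protocol)
    controller(init = function(setup) NULL,
               step = function(gs, meal_cho, t) {
                 seen_meals$cho <- c(seen_meals$cho, meal_cho)
                 list(insulin = 0, glucagon = 0)
               })
  p <- zero_flux_patient(id = "vp01")
  res <- run_trial(list(p), no_meals(start_glucose = 3.0, seed = 2),
                   watching)
  r <- res$runs[[1]]$rescues
  expect_gte(nrow(r), 1)
  expect_equal(r$time[1], 0)
  expect_equal(r$cho, rep(16, nrow(r)))
  if (nrow(r) > 1) expect_true(all(diff(r$time) >= 15))
  # rescues are never announced to the controller
  expect_equal(seen_meals$cho, rep(0, length(seen_meals$cho)))
  # and a trace that never dips below threshold triggers none
  res2 <- run_trial(list(p), no_meals(start_glucose = 10, seed = 2),
                    watching)
  expect_equal(nrow(res2$runs[[1]]$rescues), 0)
})

test_that("the open-loop reference doses basal plus announced/ICR", {
  p <- patient_parameters(w = 70, tdd = 50 / 70, basal_rate = 0.01)
  expect_equal(p$icr, 10)
  ctrl <- open_loop_controller(p, trial_protocol())
  ctrl$init(list(dosing_step = 10))
  expect_equal(ctrl$step(7, 0, 0), list(insulin = 0.1, glucagon = 0))
  expect_equal(ctrl$step(7, 60, 240), list(insulin = 6.1, glucagon = 0))
  p$icr <- NA_real_
  expect_error(open_loop_controller(p, trial_protocol()), "ICR")
})

test_that("recorded insulin equals the controller's returns exactly", {
  returned <- new.env(); returned$u <- numeric()
  factory <- function(patient, protocol) {
    base <- open_loop_controller(patient, protocol)
    controller(init = base$init,
               step = function(gs, meal_cho, t) {
                 d <- base$step(gs, meal_cho, t)
                 returned$u <- c(returned$u, d$insulin)
                 d
               })
  }
  co <- sample_cohort(cohort_spec(n_patients = 1, seed = 12))
  res <- run_trial(co, no_meals(seed = 3, arm = "open-loop"), factory)
  expect_identical(sum(res$runs[[1]]$insulin), sum(returned$u))
})

test_that("non-dual arms never deliver glucagon", {
  p <- patient_parameters(id = "vp01")
  pr <- no_meals(start_glucose = 3.6, arm = "single-hormone", seed = 9)
  res <- run_trial(list(p), pr,
                   function(pt, proto) dual_hormone_controller(pt, proto))
  expect_equal(unname(res$runs[[1]]$glucagon),
               rep(0, length(res$runs[[1]]$glucagon)))
  pr2 <- no_meals(start_glucose = 3.6, arm = "dual-hormone", seed = 9)
  res2 <- run_trial(list(p), pr2,
                    function(pt, proto) dual_hormone_controller(pt, proto))
  expect_gt(sum(res2$runs[[1]]$glucagon), 0)
})

test_that("permuting cohort order leaves every run unchanged", {
  co <- sample_cohort(cohort_spec(n_patients = 3, seed = 14))
  pr <- fixture_protocol(arm = "open-loop", seed = 6)
  pr$duration_min <- 360
  a <- run_trial(co, pr)
  b <- run_trial(co$patients[c(3, 1, 2)], pr)
  ids <- vapply(a$runs, `[[`, character(1), "id")
  ids_b <- vapply(b$runs, `[[`, character(1), "id")
  for (id in ids)
    expect_identical(a$runs[[match(id, ids)]], b$runs[[match(id, ids_b)]])
})
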