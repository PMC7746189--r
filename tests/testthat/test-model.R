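test_that("only the constant insulin source survives at the origin", {
  p <- patient_parameters(ci = 0.002)
  d <- derivatives(model_state(), p, exogenous_inputs(), 0)
  expect_equal(unname(d[["Qi"]]), 0.002)
  expect_equal(unname(d[c("Qis1", "Qis2", "Qif1", "Qif2")]), rep(0, 4))
  expect_equal(unname(d[c("x1", "x2", "x3")]), rep(0, 3))  # Ip = 0
})

test_that("plasma insulin conversion is exact and linear", {
  p <- patient_parameters(w = 70)
  expect_equal(plasma_insulin(model_state(), p), 0)
  ip1 <- plasma_insulin(model_state(Qi = 1), p)
  expect_equal(ip1, 1e6 / (190 * 70), tolerance = 1e-12)
  expect_equal(plasma_insulin(model_state(Qi = 2), p), 2 * ip1)
})

test_that("plasma glucagon reduces to background and scales linearly", {
  p <- patient_parameters()
  expect_equal(plasma_glucagon(model_state(), p), p$Cb)
  c1 <- plasma_glucagon(model_state(Qg2 = 0.01), p) - p$Cb
  c2 <- plasma_glucagon(model_state(Qg2 = 0.02), p) - p$Cb
  expect_equal(c2, 2 * c1)
})

test_that("insulin chain derivatives vanish at the hand-solved equilibrium", {
  # setting each chain equation to zero: Qis1 = u*pi/kis1, Qis2 = u*pi/kis2,
  # Qif1 = Qif2 = u*(1-pi)/kif, Qi = (u*Im + ci)/ke, x_i = Ip
  p <- patient_parameters()
  u <- 0.02
  qi <- (u * 1 + p$ci) / p$ke
  ip <- qi / (p$Vi * p$w) * 1e6
  s <- model_state(Qis1 = u * p$pi / p$kis1, Qis2 = u * p$pi / p$kis2,
                   Qif1 = u * (1 - p$pi) / p$kif,
                   Qif2 = u * (1 - p$pi) / p$kif,
                   Qi = qi, x1 = ip, x2 = ip, x3 = ip)
  d <- derivatives(s, p, exogenous_inputs(ui = u), 0)
  expect_lt(max(abs(d[1:8])), 1e-12)
})

test_that("meal appearance vanishes at ingestion and delays channel two", {
  p <- patient_parameters()
  meal <- list(time = 100, cho = 60)
  expect_equal(meal_appearance(100, meal, p), 0)
  # before the delay elapses only the first channel contributes
  tau <- p$d / 2
  um <- meal_appearance(100 + tau, meal, p)
  um1 <- p$km^2 * tau * exp(-p$km * tau) * 60 * 5551 * p$pm / p$w
  expect_equal(um, um1 * flux_at(p$fm, 100 + tau), tolerance = 1e-12)
  expect_error(meal_appearance(99, meal, p), "ingestion")
})

test_that("gut appearance integrates to the ingested carbohydrate", {
  p <- patient_parameters(fm = constant_flux(1))
  meal <- list(time = 0, cho = 75)
  total <- stats::integrate(function(t)
    vapply(t, meal_appearance, numeric(1), meal = meal, params = p),
    0, 2000, rel.tol = 1e-10)$value
  expect_equal(total, 75 * 5551 / p$w, tolerance = 1e-4)
})

test_that("EGP clamps at zero and decreases with remote insulin", {
  p <- patient_parameters()
  expect_equal(egp(10, 0, p), 10 * p$Sg)
  x_full <- 1 / (p$Se * 1e-4)            # full suppression
  expect_equal(egp(10, x_full, p), 0)
  expect_equal(egp(10, 2 * x_full, p), 0)
  xs <- seq(0, 2 * x_full, length.out = 50)
  vals <- egp(8, xs, p)
  expect_true(all(diff(vals) <= 1e-12))
  expect_true(all(vals >= 0))
})

test_that("the glucose saturation term is bounded by F01", {
  p <- patient_parameters()
  q1 <- c(0, 1, 160, 1e3, 1e6)
  term <- p$F01 * (q1 / 160) / (1 + q1 / 160)
  expect_true(all(term >= 0 & term <= p$F01))
})

test_that("invalid states are rejected with the variable named", {
  p <- patient_parameters()
  y <- model_state()
  y[3] <- -1
  expect_error(derivatives(y, p), "Qif1")
  y <- model_state()
  y[11] <- NaN
  expect_error(derivatives(y, p), "Q1")
  expect_error(model_state(Qz = 1), "unknown state")
})

test_that("the origin is a rest point without endogenous sources", {
  p <- zero_flux_patient()
  s <- integrate_model(model_state(), p, exogenous_inputs(), 0, 720)
  expect_equal(max(abs(s)), 0)
})

test_that("insulin PK after a bolus matches the analytic chain solution", {
  p <- linear_patient()
  x0 <- as.numeric(model_state(Qis1 = 3 * p$pi, Qif1 = 3 * (1 - p$pi),
                               Q1 = 7 * p$V, Gs = 7))
  for (t in c(30, 120, 480)) {
    num <- integrate_model(model_state(Qis1 = 3 * p$pi,
                                       Qif1 = 3 * (1 - p$pi),
                                       Q1 = 7 * p$V, Gs = 7),
                           p, exogenous_inputs(), 0, t,
                           rtol = 1e-10, atol = 1e-12)
    ana <- lti_solution(p, x0, t)
    expect_lt(rel_err(as.numeric(num)[1:10], ana[1:10]), 1e-6)
  }
})

test_that("sensor glucose follows the first-order step response", {
  p <- zero_flux_patient()
  g <- 7
  s0 <- model_state(Q1 = g * p$V)        # Gs starts at 0, G held at 7
  for (t in c(5, 15, 60, 240)) {
    s <- integrate_model(s0, p, exogenous_inputs(), 0, t,
                         rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(s[["Gs"]]), g * (1 - exp(-p$ks * t)),
                 tolerance = 1e-6)
  }
})

test_that("tightening tolerances converges monotonically on the fixture", {
  p <- patient_parameters()
  s0 <- init_state(p, trial_protocol())
  inp <- exogenous_inputs(ui = p$basal_rate,
                          meals = data.frame(time = 10, cho = 60),
                          clock_offset = 480)
  g_at <- function(rt, at)
    integrate_model(s0, p, inp, 0, 180, rtol = rt, atol = at)[["Q1"]] / p$V
  ref <- g_at(1e-12, 1e-14)
  e6 <- abs(g_at(1e-6, 1e-8) - ref)
  e8 <- abs(g_at(1e-8, 1e-10) - ref)
  e10 <- abs(g_at(1e-10, 1e-12) - ref)
  expect_lte(e8, e6 + 1e-12)
  expect_lte(e10, e8 + 1e-12)
  expect_lt(abs(g_at(1e-8, 1e-10) - g_at(1e-10, 1e-12)), 1e-6)
})

test_that("non-negative states stay non-negative through integration", {
  p <- patient_parameters()
  set.seed(7)
  for (i in 1:10) {
    vals <- c(runif(10, 0, 0.5), runif(1, 200, 2000), runif(1, 0, 800),
              runif(1, 2, 12))
    names(vals) <- c("Qis1", "Qis2", "Qif1", "Qif2", "Qi", "x1", "x2",
                     "x3", "Qg1", "Qg2", "Q1", "Q2", "Gs")
    y0 <- do.call(model_state, as.list(vals))
    inp <- exogenous_inputs(ui = runif(1, 0, 0.05), ug = runif(1, 0, 0.01),
                            meals = data.frame(time = 5, cho = 40))
    s <- integrate_model(y0, p, inp, 0, 120)
    expect_true(all(s >= 0))
  }
})
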