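flat_trace <- function(value, minutes = 60, step = 10)
  glucose_trace(seq(0, minutes, by = step), rep(value, minutes / step + 1))

test_that("time in range handles constant and mixed traces", {
  expect_equal(time_in_range(flat_trace(6), 4, 8), 100)
  expect_equal(time_in_range(flat_trace(12), 4, 10), 0)
  tr <- glucose_trace(c(0, 10, 20, 30), c(5, 5, 12, 3))
  expect_equal(time_in_range(tr, 4, 10), 50)
})

test_that("threshold AUC integrates rectangles and triangles exactly", {
  expect_equal(auc_outside(flat_trace(5), 4, "below"), 0)
  expect_equal(auc_outside(flat_trace(3, minutes = 60), 4, "below"), 60)
  # symmetric V-dip: depth profile -1 -> +1 -> -1 over two 10-min segments
  # crosses threshold midway, leaving a triangle of base 10 and height 1
  v <- glucose_trace(c(0, 10, 20), c(5, 3, 5))
  expect_equal(auc_outside(v, 4, "below"), 5)
  expect_equal(auc_outside(v, 4, "above"), 5)   # mirrored triangle above
  # scale equivariance: doubling the excursion depth doubles the area
  v2 <- glucose_trace(c(0, 10, 20), c(6, 2, 6))
  expect_equal(auc_outside(v2, 4, "below"), 2 * auc_outside(v, 4, "below"))
})

test_that("event counting applies the recovery hysteresis", {
  expect_equal(count_events(flat_trace(5), 3.3), 0)
  dip <- glucose_trace(seq(0, 40, 10), c(5, 3, 5, 5, 5))
  expect_equal(count_events(dip, 3.3), 1)
  # partial recovery inside the hysteresis band does not re-arm the counter
  dither <- glucose_trace(seq(0, 50, 10), c(5, 3, 3.5, 3, 3.5, 5))
  expect_equal(count_events(dither, 3.3, 0.6), 1)
  # full recovery above threshold + hysteresis starts a new event
  two <- glucose_trace(seq(0, 40, 10), c(5, 3, 4.5, 3, 5))
  expect_equal(count_events(two, 3.3, 0.6), 2)
})

test_that("cohort summary statistics are the textbook ones", {
  s <- summarize_metric(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$mean, 2.5)
  one <- summarize_metric(7)
  expect_equal(one$median, 7)
  expect_equal(one$mean, 7)
  expect_equal(one$q75 - one$q25, 0)
  expect_equal(one$sd, 0)
})

test_that("threshold nesting and band complementarity hold on random traces", {
  set.seed(42)
  for (i in 1:20) {
    tr <- glucose_trace(seq(0, 240, 5), runif(49, 2, 14))
    expect_lte(time_outside(tr, 3.1, "below"), time_outside(tr, 4, "below"))
    expect_lte(auc_outside(tr, 3.1, "below"), auc_outside(tr, 4, "below"))
    expect_lte(time_in_range(tr, 4, 8), time_in_range(tr, 4, 10))
    total <- time_outside(tr, 4, "below") + time_in_range(tr, 4, 10) +
      time_outside(tr, 10, "above")
    expect_equal(total, 100)
  }
})

test_that("refining a piecewise-linear trace barely moves the metrics", {
  t1 <- seq(0, 120, 10)
  v1 <- 7 + 4 * sin(t1 / 20)
  t2 <- seq(0, 120, 5)
  v2 <- approx(t1, v1, xout = t2)$y
  a <- glucose_trace(t1, v1)
  b <- glucose_trace(t2, v2)
  expect_equal(auc_outside(a, 10, "above"), auc_outside(b, 10, "above"),
               tolerance = 1e-10)
  expect_lt(abs(time_outside(a, 10, "above") -
                  time_outside(b, 10, "above")),
            100 / length(t1) + 1e-9)
})

test_that("malformed traces are rejected", {
  expect_error(glucose_trace(c(0, 10, 25), c(5, 5, 5)), "uniform")
  expect_error(glucose_trace(0, 5), "2")
  expect_error(glucose_trace(c(0, 10), c(5, -1)), "> 0")
})
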