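sched_h <- function() {
  s <- default_scan_schedule()
  (as.numeric(s) - as.numeric(s[1])) / 3600
}

test_that("extrema detection handles ramps and single cycles", {
  t <- sched_h()
  expect_equal(nrow(find_local_extrema(t, 0.01 * t)), 0)
  one_cycle <- 0.02 * sin(2 * pi * t / 12.5)
  ex <- find_local_extrema(t, one_cycle)
  expect_equal(sort(ex$kind), c("max", "min"))
})

test_that("extrema match the quadratic-scan prominence oracle", {
  set.seed(60)
  for (rep in 1:30) {
    n <- sample(8:40, 1)
    t <- cumsum(runif(n, 0.2, 1.5))
    v <- cumsum(rnorm(n, sd = 0.004))
    gate <- 0.003
    got <- find_local_extrema(t, v, min_prominence = gate)
    want <- oracle_extrema(t, v, gate)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$index, want$index)
      expect_equal(got$kind, want$kind)
      expect_equal(got$prominence_m, want$prominence, tolerance = 1e-12)
    }
  }
})

mk_series <- function(values, times = sched_h(), tree = "t") {
  list(tree_id = tree, times_h = times, mean_displacement = values)
}

test_that("an all-zero series is noise, exclusively", {
  cls <- classify_movement(mk_series(rep(0, 18)))
  expect_equal(cls$primary_label, "noise")
  expect_length(cls$secondary_labels, 0)
  expect_true(cls$evidence$rule_noise)
})

test_that("a 12 h sinusoid of 2 cm amplitude classifies as sleep", {
  t <- sched_h()
  cls <- classify_movement(mk_series(0.02 * sin(2 * pi * t / 12)))
  expect_equal(cls$primary_label, "sleep")
  expect_true(cls$evidence$returned_to_start)
  expect_lte(cls$evidence$n_prominent_extrema, 2)
})

test_that("a linear ramp reaching 5 cm classifies as drift", {
  t <- sched_h()
  cls <- classify_movement(mk_series(0.05 * t / max(t)))
  expect_equal(cls$primary_label, "drift")
  expect_equal(cls$evidence$n_prominent_extrema, 0)
  expect_true(cls$evidence$farthest_in_last_epochs)
})

test_that("a 3 h sinusoid of 0.75 cm amplitude classifies as oscillation", {
  t <- sched_h()
  cls <- classify_movement(mk_series(0.0075 * sin(2 * pi * t / 3)))
  expect_equal(cls$primary_label, "oscillation")
  expect_gte(cls$evidence$n_prominent_extrema, 3)
  expect_true(cls$evidence$comparable_prominences)
})

test_that("the noise gate is exclusive for any sub-threshold series", {
  set.seed(61)
  t <- sched_h()
  for (rep in 1:20) {
    v <- runif(18, -0.005, 0.005)
    v[1] <- 0
    cls <- classify_movement(mk_series(v), decompose = FALSE)
    expect_equal(cls$primary_label, "noise")
    expect_length(cls$secondary_labels, 0)
  }
})

test_that("negating a series preserves its label set", {
  set.seed(62)
  t <- sched_h()
  cases <- list(0.02 * sin(2 * pi * t / 12),
                0.05 * t / max(t),
                0.0075 * sin(2 * pi * t / 3),
                0.01 * sin(2 * pi * t / 10) + 0.002 * t)
  for (v in cases) {
    a <- classify_movement(mk_series(v), decompose = FALSE)
    b <- classify_movement(mk_series(-v), decompose = FALSE)
    expect_equal(a$primary_label, b$primary_label)
    expect_setequal(a$secondary_labels, b$secondary_labels)
  }
})

test_that("short series report sleep as not evaluable rather than false", {
  t <- sched_h()[1:6]  # 3 h span
  v <- 0.02 * sin(2 * pi * t / 12)
  cls <- classify_movement(mk_series(v, times = t), decompose = FALSE)
  expect_false(cls$evidence$sleep_evaluable)
  expect_false(cls$evidence$rule_sleep)
})

test_that("superimposed sleep + oscillation resolves deterministically with evidence", {
  # the three positive rules are mutually exclusive by extremum count
  # (0 / 1-2 / >= 3), so a superposition lands in the fallback path: primary
  # is the largest-amplitude rule and the short-period evidence is preserved
  t <- sched_h()
  v <- 0.02 * sin(2 * pi * t / 12) + 0.008 * sin(2 * pi * t / 3)
  cls <- classify_movement(mk_series(v), decompose = FALSE)
  expect_equal(cls$primary_label, "sleep")
  expect_true(cls$evidence$fallback)
  expect_gte(cls$evidence$n_prominent_extrema, 3)  # the oscillation shows
  expect_true(cls$evidence$returned_to_start)
  # repeated calls are identical (evidence reproduces the decision)
  expect_identical(cls$evidence,
                   classify_movement(mk_series(v), decompose = FALSE)$evidence)
})

test_that("decomposition is exact on its own model class", {
  t <- sched_h()
  comp <- decompose_movement(mk_series(0.004 * t))
  expect_equal(comp$drift_rate, 0.004, tolerance = 1e-6)
  expect_lte(comp$circadian_amplitude, 1e-6)
  expect_lte(comp$oscillation_amplitude, 1e-6)

  comp0 <- decompose_movement(mk_series(rep(0, 18)))
  expect_lte(abs(comp0$drift_rate), 1e-9)
  expect_lte(comp0$circadian_amplitude, 1e-9)
  expect_lte(comp0$oscillation_amplitude, 1e-9)
  expect_lte(comp0$residual_rms, 1e-12)
})

test_that("superposed components are recovered from noisy series", {
  t <- sched_h()
  true <- list(drift = 0.002, A_c = 0.015, P_c = 10, A_o = 0.006, P_o = 3)
  res <- t(vapply(1:50, function(s) {
    set.seed(1000 + s)
    phi_c <- runif(1, 0, true$P_c); phi_o <- runif(1, 0, true$P_o)
    d <- true$drift * t +
      true$A_c * sin(2 * pi * (t - phi_c) / true$P_c) +
      true$A_o * sin(2 * pi * (t - phi_o) / true$P_o)
    v <- (d - d[1]) + rnorm(18, sd = 0.001)
    comp <- decompose_movement(mk_series(v))
    c(comp$drift_rate, comp$circadian_amplitude, comp$circadian_period,
      comp$oscillation_amplitude, comp$oscillation_period)
  }, numeric(5)))
  med <- apply(res, 2, median)
  expect_lt(abs(med[2] - true$A_c) / true$A_c, 0.2)
  expect_lt(abs(med[4] - true$A_o) / true$A_o, 0.2)
  expect_lt(abs(med[3] - true$P_c), 0.5)
  expect_lt(abs(med[5] - true$P_o), 0.5)
})

test_that("time-shifting a series changes decomposition phases only", {
  t <- sched_h()
  v <- 0.01 * sin(2 * pi * t / 10) + 0.004 * sin(2 * pi * t / 3) + 0.001 * t
  a <- decompose_movement(mk_series(v))
  b <- decompose_movement(mk_series(v, times = t + 5))
  expect_equal(a$circadian_amplitude, b$circadian_amplitude, tolerance = 1e-5)
  expect_equal(a$oscillation_amplitude, b$oscillation_amplitude,
               tolerance = 1e-5)
  expect_equal(a$circadian_period, b$circadian_period, tolerance = 1e-3)
  expect_equal(a$oscillation_period, b$oscillation_period, tolerance = 1e-3)
})

test_that("classification JSON serializes labels, evidence and components", {
  t <- sched_h()
  cls <- classify_movement(mk_series(0.02 * sin(2 * pi * t / 12), tree = "x1"))
  f <- tempfile(fileext = ".json")
  write_classification_json(cls, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$tree_id, "x1")
  expect_equal(j$primary_label, "sleep")
  expect_type(j$evidence$rule_sleep, "logical")
  expect_true(is.numeric(j$components$circadian_amplitude))
})
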