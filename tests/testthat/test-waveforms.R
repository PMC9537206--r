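test_that("inlet waveform has the prescribed period, peak and notch", {
  spec <- waveform_spec(heart_rate = 70, peak_velocity = 1,
                        reverse_fraction = 0.15)
  w <- inlet_velocity_waveform(spec)
  expect_equal(w$period, 60 / 70, tolerance = 1e-12)
  # exact periodicity at sampled times
  tt <- seq(0, w$period, length.out = 37)
  expect_equal(eval_waveform(w, tt + w$period), eval_waveform(w, tt))
  # peak at mid-systole equals peak_velocity exactly
  ts <- spec$systolic_time_fraction * w$period
  expect_equal(eval_waveform(w, ts / 2), 1)
  # notch bottom equals -reverse_fraction * peak
  tn <- spec$notch_fraction * w$period
  expect_equal(eval_waveform(w, ts + tn / 2), -0.15)
  expect_gt(waveform_mean(w), 0)
  # no reverse flow when the notch depth is zero
  w0 <- inlet_velocity_waveform(waveform_spec(peak_velocity = 1,
                                              reverse_fraction = 0))
  tt <- seq(0, w0$period, length.out = 400)
  expect_gte(min(eval_waveform(w0, tt)), 0)
  expect_equal(max(eval_waveform(w0, tt)), 1, tolerance = 1e-3)
})

test_that("pressure waveform spans its extremes exactly and smoothly", {
  spec <- waveform_spec(systolic_pressure = 120, diastolic_pressure = 80)
  w <- outlet_pressure_waveform(spec)
  expect_equal(eval_waveform(w, w$period / 2), 120)
  expect_equal(eval_waveform(w, 0), 80)
  tt <- seq(0, w$period, length.out = 2000)
  pv <- eval_waveform(w, tt)
  expect_lte(max(pv), 120 + 1e-9)
  expect_gte(min(pv), 80 - 1e-9)
  m <- waveform_mean(w)
  expect_true(m > 80 && m < 120)
  # periodic closure and continuous derivative at the cycle seam
  expect_equal(eval_waveform(w, 0), eval_waveform(w, w$period))
  h <- 1e-6
  d_left <- (eval_waveform(w, w$period) - eval_waveform(w, w$period - h)) / h
  d_right <- (eval_waveform(w, h) - eval_waveform(w, 0)) / h
  # both one-sided slopes vanish at the diastolic minimum; the residual gap
  # is O(h) relative to the ~150 mmHg/s systolic upstroke
  expect_lt(abs(d_left - d_right), 1e-2)
  expect_error(waveform_spec(systolic_pressure = 70,
                             diastolic_pressure = 80), "exceed")
})

test_that("waveform means are quadrature-stable under sampling refinement", {
  spec <- waveform_spec()
  for (w in list(inlet_velocity_waveform(spec),
                 outlet_pressure_waveform(spec))) {
    m1 <- waveform_mean(w, n = 512)
    m2 <- waveform_mean(w, n = 1024)
    expect_lt(abs(m2 - m1) / abs(m2), 1e-3)
  }
})

test_that("synthetic traction patterns drive the OSI brackets", {
  expect_equal(osi(synthetic_wall_traction("constant", amplitude = 2)),
               rep(0, 8))
  expect_equal(osi(synthetic_wall_traction("reversing", amplitude = 2)),
               rep(0.5, 8))
  expect_equal(osi(synthetic_wall_traction("rotating", amplitude = 2)),
               rep(0.5, 8))
  # offset sine with amplitude < offset never changes sign -> OSI 0
  s <- synthetic_wall_traction("offset_sine", amplitude = 1, offset = 2)
  expect_equal(osi(s), rep(0, 8), tolerance = 1e-12)
  expect_error(synthetic_wall_traction("vortex"))
  expect_error(synthetic_wall_traction("constant", n_time = 3))
})

test_that("waveforms and traction series round-trip through CSV", {
  spec <- waveform_spec()
  w <- inlet_velocity_waveform(spec)
  f <- tempfile(fileext = ".csv")
  waveform_to_csv(w, f)
  w2 <- waveform_from_csv(f)
  expect_equal(w2$period, w$period)
  expect_equal(w2$units, w$units)
  tt <- seq(0, w$period, length.out = 57)
  expect_equal(eval_waveform(w2, tt), eval_waveform(w, tt),
               tolerance = 1e-4)
  s <- synthetic_wall_traction("rotating", amplitude = 1.5, n_points = 5)
  f2 <- tempfile(fileext = ".csv")
  traction_to_csv(s, f2)
  s2 <- traction_from_csv(f2)
  expect_equal(s2$position, s$position)
  expect_equal(s2$tau, s$tau)
  expect_equal(s2$period, s$period)
})
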