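# fake minimal solution carrying a probe series, for cheap extrema tests
fake_solution <- function(time, pressure, period) {
  structure(list(probe_series = data.frame(time = time,
                                           pressure_inlet = pressure),
                 period = period),
            class = "flow_solution")
}

test_that("pressure extrema follow the systole/diastole definitions", {
  T_ <- 0.8
  tt <- seq(0, T_, length.out = 101)[-101]
  # constant pressure: all three phases identical
  pc <- fake_solution(tt, rep(mmhg_to_pa(95), 100), T_)
  pe <- pressure_extrema(pc)
  expect_equal(unname(pe), rep(95, 3), tolerance = 1e-9)
  # pure sinusoid about mean m: systolic + end-diastolic = 2 m
  m <- mmhg_to_pa(100); a <- mmhg_to_pa(15)
  ps <- fake_solution(tt, m + a * sin(2 * pi * tt / T_), T_)
  pe <- pressure_extrema(ps)
  expect_equal(pe[["systolic"]] + pe[["end_diastolic"]],
               2 * pa_to_mmhg(m), tolerance = 1e-3)
})

test_that("the imposed outlet waveform is recovered at the outlet probe", {
  sol <- fx_pulsatile(0)
  pe <- pressure_extrema(sol, probe = "outlet")
  expect_equal(pe[["systolic"]], 120, tolerance = 1e-3)
  expect_equal(pe[["end_diastolic"]], 80, tolerance = 1e-3)
})

test_that("RRT order statistics respect flags", {
  prof <- index_profile(synthetic_wall_traction("constant", amplitude = 0.5,
                                                n_points = 3))
  prof$rrt <- c(1, 2, 3); prof$rrt_flag <- rep(FALSE, 3)
  s <- summarize_rrt(prof)
  expect_equal(c(s$max, s$median, s$min), c(3, 2, 1))
  expect_equal(s$n_flagged, 0)
  prof$rrt <- c(1, 50, 3); prof$rrt_flag <- c(FALSE, TRUE, FALSE)
  s <- summarize_rrt(prof)
  expect_equal(c(s$max, s$median, s$min, s$n_flagged), c(3, 2, 1, 1))
  prof$rrt_flag <- rep(TRUE, 3)
  s <- summarize_rrt(prof)
  expect_true(is.na(s$max) && is.na(s$median) && is.na(s$min))
  expect_equal(s$n_flagged, 3)
})

test_that("amplification is 1 for self-comparison and errors on zero flow", {
  sol <- fx_pulsatile(0)
  expect_equal(amplification_factor(sol, sol), 1)
  dead <- sol
  dead$probe_series$velocity_bulk_throat <- 0
  expect_error(amplification_factor(sol, dead), "zero")
})

test_that("a single-severity sweep reports the self-consistent healthy row", {
  cfg <- small_sweep_config(severities = 0)
  rep <- run_severity_sweep(cfg)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$severity, 0)
  expect_equal(rep$amplification, 1)
  expect_lt(rep$mass_balance_error, 1e-6)
})

test_that("severity sweep trends follow continuity and artifacts are written", {
  cfg <- small_sweep_config(severities = c(0, 0.5))
  d1 <- tempfile()
  r1 <- run_severity_sweep(cfg, out_dir = d1)
  # monotone amplification, close to the continuity estimate 1/(1-S)
  expect_true(all(diff(r1$amplification) > 0))
  expect_equal(r1$amplification, c(1, 2), tolerance = 0.05)
  expect_true(all(diff(r1$peak_throat_velocity) > 0))
  for (f in c("report.csv", "probes_000.csv", "probes_050.csv",
              "indices_000.csv", "indices_050.csv", "run.log")) {
    expect_true(file.exists(file.path(d1, f)))
  }
})

test_that("configuration round-trips through YAML with defaults preserved", {
  cfg <- default_config()
  cfg$severities <- c(0, 0.35)
  cfg$waveforms$peak_velocity <- 0.3
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$waveforms$peak_velocity, 0.3)
  expect_equal(back$severities, c(0, 0.35))
  expect_equal(back$rheology$mu_zero, 0.056)
  # typed constructors pick up the values
  sp <- stenoflow:::config_vessel(back, 0.35)
  expect_equal(sp$severity, 0.35)
  expect_equal(sp$inlet_radius, 2e-3)
  pr <- stenoflow:::config_props(back)
  expect_s3_class(pr$rheology, "cy_params")
})
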