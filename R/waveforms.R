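#' Cardiac waveform shape specification
#'
#' Parameters of the synthetic pulsatile boundary waveforms: an
#' inlet mean-velocity waveform with a single systolic peak and a brief
#' post-systolic reverse-flow notch, and a smooth arterial pressure waveform
#' spanning the diastolic/systolic levels. The functional forms are
#' parametric shape emulations of typical aortic waveforms; all shape
#' constants are exposed here.
#'
#' @param heart_rate Heart rate, beats per minute. The cycle period is
#'   `60/heart_rate` seconds.
#' @param peak_velocity Systolic peak of the cross-section mean velocity, m/s.
#' @param reverse_fraction Depth of the post-systolic reverse-flow notch as a
#'   fraction of `peak_velocity`, in `[0, 1)`.
#' @param systolic_pressure,diastolic_pressure Pressure extremes, mmHg.
#' @param systolic_time_fraction Fraction of the cycle occupied by the
#'   systolic ejection bump.
#' @param notch_fraction Fraction of the cycle occupied by the reverse-flow
#'   notch.
#' @param pressure_skew Phase-warp strength in `[0, 1)` that skews the
#'   pressure peak towards early systole (0 gives a symmetric bump).
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(heart_rate = 70, peak_velocity = 0.4,
                          reverse_fraction = 0.15,
                          systolic_pressure = 120, diastolic_pressure = 80,
                          systolic_time_fraction = 0.35,
                          notch_fraction = 0.08,
                          pressure_skew = 0.45) {
  stopifnot(heart_rate > 0, peak_velocity > 0,
            reverse_fraction >= 0, reverse_fraction < 1,
            systolic_time_fraction > 0, notch_fraction > 0,
            systolic_time_fraction + notch_fraction < 1,
            pressure_skew >= 0, pressure_skew < 1)
  if (systolic_pressure <= diastolic_pressure) {
    stop("systolic_pressure must exceed diastolic_pressure")
  }
  structure(
    list(heart_rate = heart_rate, peak_velocity = peak_velocity,
         reverse_fraction = reverse_fraction,
         systolic_pressure = systolic_pressure,
         diastolic_pressure = diastolic_pressure,
         systolic_time_fraction = systolic_time_fraction,
         notch_fraction = notch_fraction,
         pressure_skew = pressure_skew),
    class = "waveform_spec"
  )
}

#' Periodic boundary waveform
#'
#' One cardiac cycle of a boundary quantity with its period. Evaluation is
#' exactly periodic: `eval_waveform(w, t)` uses `t mod period`. Constructed
#' either from an analytic function (internal generators) or from samples
#' (CSV round-trip), in which case a periodic cubic spline interpolates.
#'
#' @param period Cycle period, s.
#' @param fun Function of time within `[0, period)` returning the value.
#' @param units Unit tag, e.g. `"m/s"`, `"Pa"`, `"mmHg"`.
#' @param n_samples Number of stored samples (serialization resolution).
#' @return Object of class `periodic_waveform` with fields `period`, `units`,
#'   `fun` and a `samples` data frame.
#' @export
periodic_waveform <- function(period, fun, units, n_samples = 512) {
  stopifnot(is.numeric(period), period > 0, is.function(fun))
  tt <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  structure(
    list(period = period, units = units, fun = fun,
         samples = data.frame(time = tt, value = fun(tt))),
    class = "periodic_waveform"
  )
}

#' @rdname periodic_waveform
#' @param time,value Sample times (s, within one period) and values.
#' @export
periodic_waveform_from_samples <- function(time, value, period, units) {
  stopifnot(length(time) == length(value), length(time) >= 4,
            all(diff(time) > 0), period > 0, max(time) < period)
  tt <- c(time, time[1] + period)
  vv <- c(value, value[1])
  sf <- stats::splinefun(tt, vv, method = "periodic")
  w <- periodic_waveform(period, function(t) sf(time[1] + (t - time[1]) %% period),
                         units, n_samples = length(time))
  w$samples <- data.frame(time = time, value = value)
  w
}

#' Evaluate a periodic waveform
#'
#' @param w A [periodic_waveform()].
#' @param t Time(s), s; reduced modulo the period.
#' @return Value(s) in the waveform's units.
#' @export
eval_waveform <- function(w, t) {
  stopifnot(inherits(w, "periodic_waveform"))
  w$fun(t %% w$period)
}

#' Cycle mean of a periodic waveform
#'
#' Composite-trapezoid mean over one period with periodic closure.
#'
#' @param w A [periodic_waveform()].
#' @param n Number of quadrature samples.
#' @return Scalar mean in the waveform's units.
#' @export
waveform_mean <- function(w, n = 2048) {
  tt <- seq(0, w$period, length.out = n + 1L)[seq_len(n)]
  mean(eval_waveform(w, tt))
}

#' Synthetic pulsatile inlet-velocity waveform
#'
#' Generates the cross-section mean-velocity waveform: a systolic
#' `sin^2` ejection bump peaking at `peak_velocity`, followed by a brief
#' negative notch of depth `reverse_fraction * peak_velocity`, then zero
#' diastolic flow. The waveform is continuously differentiable and has a
#' strictly positive cycle mean for `reverse_fraction < 1`.
#'
#' @param spec A [waveform_spec()].
#' @return A [periodic_waveform()] in m/s with period `60/heart_rate` s.
#' @export
inlet_velocity_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  T_ <- 60 / spec$heart_rate
  ts <- spec$systolic_time_fraction * T_
  tn <- spec$notch_fraction * T_
  vp <- spec$peak_velocity
  rf <- spec$reverse_fraction
  fun <- function(t) {
    t <- t %% T_
    v <- numeric(length(t))
    i1 <- t < ts
    v[i1] <- vp * sin(pi * t[i1] / ts)^2
    i2 <- !i1 & t < ts + tn
    v[i2] <- -rf * vp * sin(pi * (t[i2] - ts) / tn)^2
    v
  }
  periodic_waveform(T_, fun, units = "m/s")
}

#' Synthetic arterial pressure waveform
#'
#' Smooth (infinitely differentiable) periodic pressure waveform whose cycle
#' maximum equals `systolic_pressure` and minimum equals
#' `diastolic_pressure` exactly. A monotone phase warp
#' `u(t) = t/T + skew * sin(2 pi t / T) / (2 pi)` applied to a `sin^2` bump
#' skews the peak towards early systole. Values are in mmHg at this
#' interface; conversion to Pa (1 mmHg = 133.322 Pa) happens inside the
#' solver.
#'
#' @param spec A [waveform_spec()].
#' @return A [periodic_waveform()] in mmHg.
#' @export
outlet_pressure_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  T_ <- 60 / spec$heart_rate
  dia <- spec$diastolic_pressure
  sys <- spec$systolic_pressure
  k <- spec$pressure_skew
  fun <- function(t) {
    t <- t %% T_
    u <- t / T_ + k * sin(2 * pi * t / T_) / (2 * pi)
    dia + (sys - dia) * sin(pi * u)^2
  }
  periodic_waveform(T_, fun, units = "mmHg")
}

MMHG_TO_PA <- 133.322

#' Convert between mmHg and Pa
#'
#' @param x Pressure value(s).
#' @return Converted value(s); 1 mmHg = 133.322 Pa.
#' @export
mmhg_to_pa <- function(x) x * MMHG_TO_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_TO_PA

#' Time-resolved wall-traction series
#'
#' Wall-shear-stress vectors at wall sample points over one cardiac cycle on
#' a uniform time grid. The time grid holds `n` samples at
#' `t_k = k * period / n`, `k = 0 .. n-1`; quadrature in the index chain
#' wraps periodically.
#'
#' @param position Strictly increasing wall arc-length positions, m.
#' @param time Uniform time samples within `[0, period)`, s; at least 4.
#' @param tau Numeric array `[n_position, n_time, n_component]` of traction
#'   vectors, Pa (2 or 3 components).
#' @param period Cycle period, s.
#' @return Object of class `wall_traction_series`.
#' @export
wall_traction_series <- function(position, time, tau, period) {
  stopifnot(length(time) >= 4, all(diff(position) > 0),
            is.array(tau), length(dim(tau)) == 3,
            dim(tau)[1] == length(position), dim(tau)[2] == length(time),
            dim(tau)[3] %in% c(2L, 3L), period > 0)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("time samples must be uniformly spaced")
  }
  exp_dt <- period / length(time)
  if (abs(dt[1] - exp_dt) > 1e-6 * exp_dt) {
    stop("time grid must cover exactly one period (n uniform samples)")
  }
  structure(list(position = position, time = time, tau = tau, period = period),
            class = "wall_traction_series")
}

#' Synthetic wall-traction fixtures
#'
#' Generates analytic wall-traction series for testing the index chain
#' without running the flow solver. Patterns:
#' \describe{
#'   \item{constant}{fixed vector `(amplitude, 0)`: OSI = 0 downstream.}
#'   \item{reversing}{zero-mean sinusoid `(amplitude * sin(w t), 0)`:
#'     OSI = 0.5.}
#'   \item{offset_sine}{mean `offset` plus sinusoid of the given amplitude
#'     along one direction; never changes sign when `amplitude < offset`,
#'     so OSI = 0 in that regime.}
#'   \item{rotating}{vector of constant magnitude rotating uniformly in the
#'     tangent plane; its time integral vanishes, so OSI = 0.5.}
#' }
#'
#' @param pattern One of `"constant"`, `"reversing"`, `"offset_sine"`,
#'   `"rotating"`.
#' @param amplitude Traction amplitude, Pa.
#' @param n_points Number of wall sample points.
#' @param n_time Number of uniform time samples per cycle (default 100,
#'   matching the WSS export convention).
#' @param period Cycle period, s (default one 70 bpm cycle).
#' @param offset Mean level for `offset_sine`, Pa (default `2 * amplitude`).
#' @return A [wall_traction_series()].
#' @export
synthetic_wall_traction <- function(pattern = c("constant", "reversing",
                                                "offset_sine", "rotating"),
                                    amplitude = 1, n_points = 8,
                                    n_time = 100, period = 60 / 70,
                                    offset = 2 * amplitude) {
  pattern <- match.arg(pattern)
  stopifnot(n_time >= 4, n_points >= 1, amplitude >= 0, period > 0)
  tt <- (seq_len(n_time) - 1L) * period / n_time
  ph <- 2 * pi * tt / period
  t1 <- switch(pattern,
    constant    = rep(amplitude, n_time),
    reversing   = amplitude * sin(ph),
    offset_sine = offset + amplitude * sin(ph),
    rotating    = amplitude * cos(ph)
  )
  t2 <- if (pattern == "rotating") amplitude * sin(ph) else numeric(n_time)
  tau <- array(0, dim = c(n_points, n_time, 2L))
  tau[, , 1] <- matrix(t1, n_points, n_time, byrow = TRUE)
  tau[, , 2] <- matrix(t2, n_points, n_time, byrow = TRUE)
  wall_traction_series(position = seq(0, by = 1e-3, length.out = n_points),
                       time = tt, tau = tau, period = period)
}

#' Waveform CSV round-trip
#'
#' Writes/reads a waveform as a two-column CSV (`time_s`, `value_<units>`).
#'
#' @param w A [periodic_waveform()].
#' @param path File path.
#' @return `waveform_to_csv` returns `path` invisibly; `waveform_from_csv`
#'   returns a [periodic_waveform()] interpolating the samples.
#' @export
waveform_to_csv <- function(w, path) {
  stopifnot(inherits(w, "periodic_waveform"))
  unit_tag <- gsub("[^A-Za-z0-9]+", "_", w$units)
  df <- w$samples
  names(df) <- c("time_s", paste0("value_", unit_tag))
  utils::write.csv(cbind(df, period_s = w$period), path, row.names = FALSE)
  invisible(path)
}

#' @rdname waveform_to_csv
#' @export
waveform_from_csv <- function(path) {
  df <- utils::read.csv(path)
  vcol <- grep("^value_", names(df), value = TRUE)
  stopifnot(length(vcol) == 1, "time_s" %in% names(df),
            "period_s" %in% names(df))
  units <- gsub("_", "/", sub("^value_", "", vcol), fixed = TRUE)
  periodic_waveform_from_samples(df$time_s, df[[vcol]],
                                 period = df$period_s[1], units = units)
}

#' Wall-traction CSV round-trip
#'
#' Long format with columns `position_m`, `time_s`, `tau_t1_Pa`, `tau_t2_Pa`
#' (and `tau_t3_Pa` for 3-component series), plus `period_s`.
#'
#' @param series A [wall_traction_series()].
#' @param path File path.
#' @return `traction_to_csv` returns `path` invisibly; `traction_from_csv`
#'   returns a [wall_traction_series()].
#' @export
traction_to_csv <- function(series, path) {
  stopifnot(inherits(series, "wall_traction_series"))
  nc <- dim(series$tau)[3]
  grid <- expand.grid(ti = seq_along(series$time),
                      pi_ = seq_along(series$position))
  df <- data.frame(position_m = series$position[grid$pi_],
                   time_s = series$time[grid$ti])
  for (c_ in seq_len(nc)) {
    df[[paste0("tau_t", c_, "_Pa")]] <-
      series$tau[cbind(grid$pi_, grid$ti, c_)]
  }
  df$period_s <- series$period
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname traction_to_csv
#' @export
traction_from_csv <- function(path) {
  df <- utils::read.csv(path)
  tcols <- grep("^tau_t[0-9]+_Pa$", names(df), value = TRUE)
  pos <- sort(unique(df$position_m))
  tt <- sort(unique(df$time_s))
  tau <- array(NA_real_, dim = c(length(pos), length(tt), length(tcols)))
  ip <- match(df$position_m, pos)
  it <- match(df$time_s, tt)
  for (c_ in seq_along(tcols)) {
    tau[cbind(ip, it, c_)] <- df[[tcols[c_]]]
  }
  wall_traction_series(pos, tt, tau, period = df$period_s[1])
}
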