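#' Peak-velocity amplification factor
#'
#' Ratio of the peak cross-section mean (bulk) velocity magnitude at a
#' probe station over the final cycle to the same quantity in the healthy
#' reference run. The bulk velocity is the quantity governed by
#' incompressible continuity: the quasi-steady estimate at the throat is
#' `1 / (1 - severity)`, i.e. about 2 at 50% area severity: stenoses beyond
#' 50% amplify the peak to at least twice the healthy wave. (The centerline
#' velocity is also recorded in the probe series; its amplification is
#' weaker because the accelerated jet flattens the velocity profile.)
#'
#' @param solution A [run_simulation()] result for the stenosed vessel.
#' @param healthy The matching healthy (severity 0) [run_simulation()]
#'   result with identical waveforms and probes.
#' @param probe Probe name (default `"throat"`).
#' @return Dimensionless amplification factor (1 for identical solutions).
#' @export
amplification_factor <- function(solution, healthy, probe = "throat") {
  col <- paste0("velocity_bulk_", probe)
  stopifnot(col %in% names(solution$probe_series),
            col %in% names(healthy$probe_series))
  peak_h <- max(abs(healthy$probe_series[[col]]))
  if (peak_h == 0) stop("healthy peak velocity is zero at this probe")
  max(abs(solution$probe_series[[col]])) / peak_h
}

#' Pressure extrema over the cardiac cycle
#'
#' Systolic pressure is the cycle maximum, end-diastolic the cycle minimum,
#' and mid-diastolic the value at the temporal midpoint of the diastolic
#' interval, whose start is `decay_fraction` of a cycle after the systolic
#' peak and whose end is the cycle end.
#'
#' @param solution A [run_simulation()] result.
#' @param probe Probe name (default `"inlet"`); `"outlet"` probes the
#'   imposed outlet waveform.
#' @param decay_fraction Fraction of the cycle between the systolic peak and
#'   the start of diastole.
#' @return Named numeric vector `c(systolic, mid_diastolic, end_diastolic)`
#'   in mmHg.
#' @export
pressure_extrema <- function(solution, probe = "inlet",
                             decay_fraction = 0.15) {
  col <- paste0("pressure_", probe)
  stopifnot(col %in% names(solution$probe_series))
  tt <- solution$probe_series$time
  pp <- solution$probe_series[[col]]
  T_ <- solution$period
  t_peak <- tt[which.max(pp)]
  t_start <- t_peak + decay_fraction * T_
  t_mid <- ((t_start + T_) / 2) %% T_
  # periodic linear interpolation at t_mid
  tt2 <- c(tt, T_)
  pp2 <- c(pp, pp[1])
  p_mid <- stats::approx(tt2, pp2, xout = t_mid)$y
  pa_to_mmhg(c(systolic = max(pp), mid_diastolic = p_mid,
               end_diastolic = min(pp)))
}

#' Order statistics of an RRT profile
#'
#' Maximum, median and minimum of the finite (unflagged) RRT values; flagged
#' (singular/capped) positions are counted separately. If every position is
#' flagged the values are reported absent (`NA`).
#'
#' @param profile An [index_profile()].
#' @return List with `max`, `median`, `min` (1/Pa) and `n_flagged`.
#' @export
summarize_rrt <- function(profile) {
  stopifnot(inherits(profile, "index_profile"), nrow(profile) > 0)
  ok <- !profile$rrt_flag
  if (!any(ok)) {
    return(list(max = NA_real_, median = NA_real_, min = NA_real_,
                n_flagged = sum(!ok)))
  }
  v <- profile$rrt[ok]
  list(max = max(v), median = stats::median(v), min = min(v),
       n_flagged = sum(!ok))
}

#' Run the cross-severity experiment
#'
#' Runs [run_simulation()] for the healthy vessel and each requested
#' stenosis severity with identical waveforms and grid resolution, then
#' assembles the cross-severity report: peak throat velocity and its
#' amplification over healthy, inlet-probe pressure extrema, wall-index
#' maxima and RRT order statistics, and the periodicity residual. The whole
#' pipeline is deterministic: identical configurations give bit-identical
#' report files.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `report.csv`, per-severity `probes_<severity>.csv` and
#'   `indices_<severity>.csv`, and a `run.log`.
#' @param vtk Also dump final-cycle VTK fields (`fields_c<cycle>_t<index>.vtk`)
#'   per severity when `out_dir` is given.
#' @param quiet Suppress progress messages.
#' @return Object of class `severity_report`: a data frame (one row per
#'   severity) with the solutions attached as attribute `solutions` and the
#'   pressure/RRT rank correlation as attribute `spearman_pressure_rrt`.
#' @export
run_severity_sweep <- function(config = default_config(), out_dir = NULL,
                               vtk = FALSE, quiet = TRUE) {
  severities <- sort(unique(as.numeric(config$severities)))
  stopifnot(length(severities) >= 1, all(severities >= 0),
            all(severities < 1))
  wspec <- config_waveform_spec(config)
  bcs <- list(inlet = inlet_velocity_waveform(wspec),
              outlet = outlet_pressure_waveform(wspec))
  props <- config_props(config)
  scfg <- config_solver(config)
  eps <- config$indices$epsilon
  t0 <- Sys.time()
  log_lines <- c("stenoflow severity sweep",
                 paste0("severities: ", paste(severities, collapse = ", ")))
  # healthy reference is always run (reused if severity 0 is requested)
  run_one <- function(s) {
    grid <- build_grid(config_vessel(config, s),
                       n_axial = config$grid$n_axial,
                       n_radial = config$grid$n_radial,
                       growth_rate = config$grid$growth_rate)
    if (!quiet) message(sprintf("running severity %.2f ...", s))
    sol <- tryCatch(
      run_simulation(grid, scfg, props, bcs),
      error = function(e) stop(sprintf("severity %.2f failed: %s",
                                       s, conditionMessage(e)), call. = FALSE))
    sol
  }
  healthy <- run_one(0)
  sols <- lapply(severities, function(s) if (s == 0) healthy else run_one(s))
  names(sols) <- sprintf("%g", severities)
  rows <- lapply(seq_along(severities), function(k) {
    s <- severities[k]; sol <- sols[[k]]
    prof <- index_profile(sol$traction, epsilon = eps)
    rs <- summarize_rrt(prof)
    pe <- pressure_extrema(sol, "inlet",
                           decay_fraction = config$report$decay_fraction)
    data.frame(
      severity = s,
      peak_throat_velocity = max(abs(sol$probe_series$velocity_bulk_throat)),
      amplification = amplification_factor(sol, healthy, "throat"),
      p_systolic_mmHg = pe[["systolic"]],
      p_mid_diastolic_mmHg = pe[["mid_diastolic"]],
      p_end_diastolic_mmHg = pe[["end_diastolic"]],
      tawss_max_Pa = max(prof$tawss),
      osi_max = max(prof$osi),
      rrt_max = rs$max, rrt_median = rs$median, rrt_min = rs$min,
      rrt_flagged = rs$n_flagged,
      periodicity_residual = sol$periodicity_residual,
      mass_balance_error = mass_balance_error(sol)
    )
  })
  report <- do.call(rbind, rows)
  rho_sp <- if (nrow(report) >= 3) {
    suppressWarnings(stats::cor(report$p_systolic_mmHg, report$rrt_max,
                                method = "spearman"))
  } else NA_real_
  report <- structure(report, class = c("severity_report", "data.frame"),
                      spearman_pressure_rrt = rho_sp)
  attr(report, "solutions") <- sols
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    for (k in seq_along(severities)) {
      tag <- sprintf("%03d", round(100 * severities[k]))
      utils::write.csv(sols[[k]]$probe_series,
                       file.path(out_dir, paste0("probes_", tag, ".csv")),
                       row.names = FALSE)
      indices_to_csv(index_profile(sols[[k]]$traction, epsilon = eps),
                     file.path(out_dir, paste0("indices_", tag, ".csv")))
      if (vtk) write_solution_vtk(sols[[k]], out_dir, tag = tag)
    }
    log_lines <- c(log_lines,
                   sprintf("elapsed_s: %.1f",
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   sprintf("spearman_pressure_rrt: %s", format(rho_sp)),
                   vapply(seq_along(sols), function(k) {
                     sprintf("severity %g: div_residual %.3e, periodicity %.4f",
                             severities[k], sols[[k]]$div_residual,
                             sols[[k]]$periodicity_residual)
                   }, character(1)),
                   unlist(lapply(sols, function(s) s$warnings)))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}
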