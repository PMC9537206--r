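#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_severity_sweep()] and the command
#' line interface; round-trips to YAML. Units at this interface are
#' clinical/engineering (mm, mmHg, bpm); everything is SI internally.
#' The defaults define the study conditions: an idealized 2 mm radius,
#' 40 mm long vessel with a 6 mm stenosis bump centered at 20 mm, a 70 bpm
#' inlet waveform peaking at 0.4 m/s mean velocity with a 15% reverse-flow
#' notch, a 120/80 mmHg outlet pressure waveform, Carreau-Yasuda blood with
#' density 1060 kg/m^3, and severities 0/25/35/50/65% area reduction.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(radius_mm = 2, length_mm = 40, stenosis_center_mm = 20,
                    stenosis_length_mm = 6),
    severities = c(0, 0.25, 0.35, 0.50, 0.65),
    grid = list(n_axial = 96, n_radial = 24, growth_rate = 1.2),
    rheology = list(model = "carreau_yasuda", mu_zero = 0.056,
                    mu_inf = 0.0035, lambda_time = 3.313, n_index = 0.3568,
                    a_exponent = 2, density = 1060),
    waveforms = list(heart_rate = 70, peak_velocity = 0.4,
                     reverse_fraction = 0.15, systolic_pressure = 120,
                     diastolic_pressure = 80, systolic_time_fraction = 0.35,
                     notch_fraction = 0.08, pressure_skew = 0.45),
    solver = list(dt = 0.01, n_cycles = 3, picard_tol = 0.1,
                  div_tol = 1e-8, max_inner_iterations = 60),
    indices = list(epsilon = 1e-3),
    report = list(decay_fraction = 0.15)
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]
#' (missing keys keep their defaults).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' @rdname read_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# configuration -> typed objects
config_vessel <- function(config, severity) {
  g <- config$geometry
  stenosed_vessel_spec(inlet_radius = g$radius_mm * 1e-3,
                       length = g$length_mm * 1e-3,
                       stenosis_center = g$stenosis_center_mm * 1e-3,
                       stenosis_length = g$stenosis_length_mm * 1e-3,
                       severity = severity)
}

config_props <- function(config) {
  r <- config$rheology
  rheo <- if (identical(r$model, "newtonian")) {
    newtonian_viscosity(mu = if (!is.null(r$mu)) r$mu else r$mu_inf)
  } else {
    cy_params(mu_zero = r$mu_zero, mu_inf = r$mu_inf,
              lambda_time = r$lambda_time, n_index = r$n_index,
              a_exponent = r$a_exponent)
  }
  blood_properties(density = r$density, rheology = rheo)
}

config_waveform_spec <- function(config) {
  w <- config$waveforms
  waveform_spec(heart_rate = w$heart_rate, peak_velocity = w$peak_velocity,
                reverse_fraction = w$reverse_fraction,
                systolic_pressure = w$systolic_pressure,
                diastolic_pressure = w$diastolic_pressure,
                systolic_time_fraction = w$systolic_time_fraction,
                notch_fraction = w$notch_fraction,
                pressure_skew = w$pressure_skew)
}

config_solver <- function(config) {
  s <- config$solver
  solver_config(dt = s$dt, n_cycles = s$n_cycles, picard_tol = s$picard_tol,
                div_tol = s$div_tol,
                max_inner_iterations = s$max_inner_iterations)
}
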