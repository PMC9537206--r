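# Shared fixtures, memoized so expensive solver runs happen once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (!exists(key, envir = .fixtures)) assign(key, make(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# wall shear stress of a converged steady state at mid-vessel
steady_wss <- function(grid, state, props) {
  tau <- stenoflow:::wall_traction_instant(grid, state$u, state$v, props)
  tau[round(grid$nz / 2)]
}

# steady Poiseuille solve in a straight tube (parabolic inlet)
fx_poiseuille <- function(n_radial, growth_rate = 1.2, U = 0.05,
                          mu = 0.0035) {
  key <- sprintf("pois_%d_%g_%g_%g", n_radial, growth_rate, U, mu)
  memo(key, function() {
    grid <- build_grid(stenosed_vessel_spec(severity = 0),
                       n_axial = 24, n_radial = n_radial,
                       growth_rate = growth_rate)
    cfg <- solver_config(steady_tol = 1e-9, max_steady_steps = 900)
    props <- blood_properties(1060, newtonian_viscosity(mu))
    st <- run_steady(grid, cfg, props, inflow = U, p_out = 0)
    list(grid = grid, state = st, props = props, U = U, mu = mu)
  })
}

poiseuille_centerline_error <- function(fx) {
  grid <- fx$grid
  i <- round(grid$nz / 2)
  uc <- (fx$state$u[i, ] + fx$state$u[i + 1, ]) / 2
  ucl <- stenoflow:::centerline_value(grid, uc)
  abs(ucl / fx$U - 2) / 2
}

# small pulsatile run (coarse, quick) at a given severity
fx_pulsatile <- function(severity, n_axial = 48, n_radial = 16,
                         n_cycles = 2) {
  key <- sprintf("puls_%g_%d_%d_%d", severity, n_axial, n_radial, n_cycles)
  memo(key, function() {
    cfg <- default_config()
    cfg$grid$n_axial <- n_axial
    cfg$grid$n_radial <- n_radial
    cfg$solver$n_cycles <- n_cycles
    grid <- build_grid(stenoflow:::config_vessel(cfg, severity),
                       n_axial, n_radial, cfg$grid$growth_rate)
    wspec <- stenoflow:::config_waveform_spec(cfg)
    bcs <- list(inlet = inlet_velocity_waveform(wspec),
                outlet = outlet_pressure_waveform(wspec))
    run_simulation(grid, stenoflow:::config_solver(cfg),
                   stenoflow:::config_props(cfg), bcs)
  })
}

# quick severity-sweep configuration (coarse) for pipeline tests
small_sweep_config <- function(severities = c(0, 0.5)) {
  cfg <- default_config()
  cfg$severities <- severities
  cfg$grid$n_axial <- 32
  cfg$grid$n_radial <- 12
  cfg$solver$n_cycles <- 2
  cfg
}
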