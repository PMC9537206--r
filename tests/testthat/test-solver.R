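# Solver verification against analytic oracles. Straight-tube cases use the
# mapped grid with identity metrics, so they exercise the discretization the
# stenosed runs rely on.

test_that("a fluid at rest under uniform pressure stays at rest", {
  grid <- build_grid(stenosed_vessel_spec(severity = 0.5), 32, 12)
  cfg <- solver_config()
  props <- blood_properties(1060, cy_params())
  bcs <- list(inlet = function(r, t) 0 * r, outlet = function(t) 1000,
              period = 0.857)
  st <- flow_state(grid, p = matrix(1000, grid$nz, grid$nr), p_out = 1000)
  for (k in 1:3) st <- advance_step(st, cfg, props, bcs, grid)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
})

test_that("steady Poiseuille flow reproduces its closed forms within 1%", {
  fx <- fx_poiseuille(n_radial = 16)
  expect_lt(poiseuille_centerline_error(fx), 0.01)
  wss <- steady_wss(fx$grid, fx$state, fx$props)
  expect_equal(wss, 4 * fx$mu * fx$U / fx$grid$spec$inlet_radius,
               tolerance = 0.01)
  # radial velocity is parasitic in a fully developed tube
  expect_lt(max(abs(fx$state$v)), 1e-3 * fx$U)
})

test_that("observed spatial order of accuracy on Poiseuille is >= 1.8", {
  errs <- vapply(c(8, 16, 32),
                 function(nr) poiseuille_centerline_error(fx_poiseuille(nr)),
                 numeric(1))
  if (max(errs) < 1e-10) succeed("scheme exact on this family") else {
    orders <- log2(errs[-3] / errs[-1])
    expect_gte(min(orders), 1.8)
  }
})

test_that("pulsatile Newtonian flow matches the Womersley solution", {
  R <- 2e-3; rho <- 1060; mu <- 0.0035; A <- 2000
  alpha <- 4
  om <- alpha^2 * mu / (rho * R^2)
  Tp <- 2 * pi / om
  grid <- build_grid(stenosed_vessel_spec(severity = 0), 16, 32,
                     growth_rate = 1.2)
  inlet <- function(r, t) womersley_profile(R, rho, mu, A, om, t, r)
  bcs <- list(inlet = inlet, outlet = function(t) 0, period = Tp)
  cfg <- solver_config(dt = Tp / 100, n_cycles = 2)
  props <- blood_properties(rho, newtonian_viscosity(mu))
  L <- grid$spec$length
  init <- list(u = function(z, r) womersley_profile(R, rho, mu, A, om, 0, r),
               p = function(z) A * (L - z))
  sol <- run_simulation(grid, cfg, props, bcs, init = init)
  i <- 8
  num <- 0; den <- 0
  for (k in seq_len(100)) {
    t <- sol$t_final0 + (k - 1) * Tp / 100
    u <- stenoflow:::interp_field(sol$times, sol$states, t, "u")
    uc <- (u[i, ] + u[i + 1, ]) / 2
    ua <- womersley_profile(R, rho, mu, A, om, t, grid$ec * R)
    num <- num + sum((uc - ua)^2)
    den <- den + sum(ua^2)
  }
  expect_lt(sqrt(num / den), 0.02)
  expect_lt(mass_balance_error(sol), 1e-6)
})

test_that("the analytic Womersley profile obeys its limits", {
  R <- 2e-3; rho <- 1060; mu <- 0.0035
  r <- seq(0, R, length.out = 9)
  # alpha -> 0: quasi-steady Poiseuille for the instantaneous gradient
  om0 <- 0.1^2 * mu / (rho * R^2)
  u0 <- womersley_profile(R, rho, mu, 100, om0, 0, r)
  expect_equal(u0, 100 * (R^2 - r^2) / (4 * mu), tolerance = 0.01)
  # no slip at the wall, at any time
  expect_equal(womersley_profile(R, rho, mu, 100, om0, 0.37, R), 0)
  # alpha = 10: inertia attenuates the centerline amplitude
  om10 <- 10^2 * mu / (rho * R^2)
  tt <- seq(0, 2 * pi / om10, length.out = 181)
  amp <- max(abs(vapply(tt, function(t)
    womersley_profile(R, rho, mu, 100, om10, t, 0), numeric(1))))
  expect_lt(amp, 100 * R^2 / (4 * mu))
})

test_that("pulsatile runs conserve mass and satisfy the divergence contract", {
  sol <- fx_pulsatile(0.5)
  expect_lt(mass_balance_error(sol), 1e-6)
  expect_lt(sol$div_residual, sol$config$div_tol)
  expect_lt(sol$periodicity_residual, 0.02)
})

test_that("the inlet probe is boundary-imposed, identical across severities", {
  s0 <- fx_pulsatile(0)
  s25 <- fx_pulsatile(0.25)
  expect_equal(s25$probe_series$velocity_bulk_inlet,
               s0$probe_series$velocity_bulk_inlet, tolerance = 1e-6)
})

test_that("wall traction reverses sign with the near-wall flow", {
  sol <- fx_pulsatile(0)
  tau <- sol$traction$tau[2, , 1]  # near-inlet station over the cycle
  expect_gt(max(tau), 0)   # forward shear in systole
  expect_lt(min(tau), 0)   # reversed shear in the notch
})

test_that("steady shear-thinning WSS lies between its Newtonian bounds", {
  grid <- build_grid(stenosed_vessel_spec(severity = 0), 24, 24,
                     growth_rate = 1.2)
  cfg <- solver_config(steady_tol = 1e-8, max_steady_steps = 800)
  U <- 0.1
  wss_for <- function(rheo) {
    props <- blood_properties(1060, rheo)
    st <- run_steady(grid, cfg, props, inflow = U, p_out = 0)
    steady_wss(grid, st, props)
  }
  w_cy <- wss_for(cy_params())
  w_lo <- wss_for(newtonian_viscosity(0.0035))
  w_hi <- wss_for(newtonian_viscosity(0.056))
  expect_gt(w_cy, w_lo)
  expect_lt(w_cy, w_hi)
})

test_that("creeping-flow traction scales linearly with the inflow", {
  f1 <- fx_poiseuille(16, U = 1e-6)
  f2 <- fx_poiseuille(16, U = 2e-6)
  w1 <- steady_wss(f1$grid, f1$state, f1$props)
  w2 <- steady_wss(f2$grid, f2$state, f2$props)
  expect_equal(w2 / w1, 2, tolerance = 0.01)
})
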