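test_that("wall radius honors the area-severity definition", {
  sp <- stenosed_vessel_spec(inlet_radius = 2e-3, severity = 0.5)
  r0 <- sp$inlet_radius
  # throat area exactly halved at 50% severity
  expect_equal(wall_radius(sp, sp$stenosis_center), r0 / sqrt(2))
  # outside the bump support the vessel is exactly cylindrical
  sp65 <- stenosed_vessel_spec(severity = 0.65)
  z_out <- sp65$stenosis_center + sp65$stenosis_length / 2 + 1e-6
  expect_equal(wall_radius(sp65, z_out), sp65$inlet_radius)
  expect_equal(wall_radius(sp65, 0), sp65$inlet_radius)
  # healthy vessel is a cylinder everywhere
  sph <- stenosed_vessel_spec(severity = 0)
  zz <- seq(0, sph$length, length.out = 33)
  expect_equal(wall_radius(sph, zz), rep(sph$inlet_radius, 33))
  expect_error(wall_radius(sp, -1e-3), "outside")
  expect_error(stenosed_vessel_spec(severity = 1))
})

test_that("wall slope matches a finite-difference check", {
  sp <- stenosed_vessel_spec(severity = 0.65)
  zz <- seq(sp$stenosis_center - 2e-3, sp$stenosis_center + 2e-3,
            length.out = 21)
  h <- 1e-8
  fd <- (wall_radius(sp, zz + h) - wall_radius(sp, zz - h)) / (2 * h)
  expect_equal(stenoflow:::wall_radius_deriv(sp, zz), fd, tolerance = 1e-5)
})

test_that("grid cells partition each cross-section exactly", {
  sp <- stenosed_vessel_spec(severity = 0.65)
  g <- build_grid(sp, n_axial = 32, n_radial = 12, growth_rate = 1.2)
  for (i in c(1, 16, 33)) {
    area_sum <- sum(pi * g$Rf[i]^2 * g$ring_frac)
    expect_equal(area_sum, pi * g$Rf[i]^2, tolerance = 1e-10)
  }
  expect_true(all(diff(g$zf) > 0))
  expect_true(all(g$Rf > 0))
})

test_that("radial refinement and clustering behave as documented", {
  sp <- stenosed_vessel_spec(severity = 0)
  g1 <- build_grid(sp, 16, 8, growth_rate = 1)
  g2 <- build_grid(sp, 16, 16, growth_rate = 1)
  # uniform clustering: all axial stations share identical radial spacing,
  # and doubling n_radial halves the maximum spacing
  expect_equal(max(diff(g1$ef)), 2 * max(diff(g2$ef)))
  expect_equal(diff(range(g1$def)), 0)
  # clustered grid concentrates cells at the wall
  gc <- build_grid(sp, 16, 16, growth_rate = 1.2)
  expect_lt(gc$def[16], gc$def[1])
  expect_error(build_grid(sp, 8, 8), "minimum")
  expect_error(build_grid(sp, 16, 4), "minimum")
  expect_error(build_grid(sp, 16, 8, growth_rate = 0.8))
})

test_that("severity is recovered from the built grid", {
  for (s in c(0, 0.25, 0.65)) {
    sp <- stenosed_vessel_spec(severity = s)
    g <- build_grid(sp, 96, 12)  # even n_axial puts a face at the throat
    expect_equal(grid_severity(g), s, tolerance = 1e-6)
  }
})

test_that("grid writes a readable legacy VTK file", {
  g <- build_grid(stenosed_vessel_spec(severity = 0.5), 16, 8)
  f <- tempfile(fileext = ".vtk")
  write_vtk_grid(g, f, point_data = list(ones = matrix(1, 17, 9)))
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("DIMENSIONS 17 9 1", lines)))
  expect_true(any(grepl("POINT_DATA", lines)))
})
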