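#' Idealized stenosed-vessel specification
#'
#' Axisymmetric vessel of constant inlet radius with a smooth cosine-bump
#' area reduction. Severity is defined as the fractional reduction of
#' cross-sectional AREA at the throat: the throat area equals
#' `(1 - severity)` times the inlet area exactly, so quasi-steady continuity
#' predicts a mean-velocity amplification of `1 / (1 - severity)` there.
#'
#' @param inlet_radius Healthy lumen radius, m.
#' @param length Vessel length, m.
#' @param stenosis_center Axial position of the throat, m.
#' @param stenosis_length Axial extent of the bump (compact support), m.
#'   Physiological plaque lengths of a few millimetres (2-6 mm) are typical.
#' @param severity Area-reduction fraction in `[0, 1)`; 0 is the healthy
#'   vessel.
#' @return Object of class `stenosed_vessel_spec`.
#' @export
stenosed_vessel_spec <- function(inlet_radius = 2e-3, length = 40e-3,
                                 stenosis_center = 20e-3,
                                 stenosis_length = 6e-3,
                                 severity = 0) {
  stopifnot(inlet_radius > 0, length > 0,
            stenosis_length > 0, stenosis_length <= length,
            severity >= 0, severity < 1,
            stenosis_center >= 0, stenosis_center <= length)
  structure(
    list(inlet_radius = inlet_radius, length = length,
         stenosis_center = stenosis_center,
         stenosis_length = stenosis_length, severity = severity),
    class = "stenosed_vessel_spec"
  )
}

#' Wall radius of the stenosed vessel
#'
#' \deqn{r(z) = R_0\sqrt{1 - S\,b(z)},\qquad
#'  b(z) = \tfrac12\left(1 + \cos\frac{2\pi(z - z_c)}{L_s}\right)}
#' for \eqn{|z - z_c| \le L_s/2} and \eqn{b = 0} elsewhere. The bump is
#' continuously differentiable everywhere and the healthy sections are
#' exactly cylindrical; at the throat the cross-sectional area is exactly
#' `(1 - severity)` times the inlet area.
#'
#' @param spec A [stenosed_vessel_spec()].
#' @param z Axial position(s), m, within `[0, length]`.
#' @return Wall radius r(z), m.
#' @export
wall_radius <- function(spec, z) {
  stopifnot(inherits(spec, "stenosed_vessel_spec"))
  if (any(z < -1e-12 | z > spec$length + 1e-12)) {
    stop("z outside the vessel [0, length]")
  }
  b <- bump_profile(spec, z)
  spec$inlet_radius * sqrt(1 - spec$severity * b)
}

# smooth compact-support cosine bump, b(z_c) = 1
bump_profile <- function(spec, z) {
  x <- z - spec$stenosis_center
  b <- numeric(length(z))
  inside <- abs(x) <= spec$stenosis_length / 2
  b[inside] <- 0.5 * (1 + cos(2 * pi * x[inside] / spec$stenosis_length))
  b
}

# analytic d r / d z (used for grid metrics; avoids finite-difference noise)
wall_radius_deriv <- function(spec, z) {
  x <- z - spec$stenosis_center
  inside <- abs(x) <= spec$stenosis_length / 2
  db <- numeric(length(z))
  db[inside] <- -(pi / spec$stenosis_length) *
    sin(2 * pi * x[inside] / spec$stenosis_length)
  b <- bump_profile(spec, z)
  -spec$inlet_radius * spec$severity * db / (2 * sqrt(1 - spec$severity * b))
}

#' Structured axisymmetric grid
#'
#' Builds the body-fitted structured grid for the solver: axial cell faces
#' `z_f` (uniform) and normalized radial faces `eta_f` in `[0, 1]`, with the
#' physical radius at any station given by `eta * r_wall(z)`. Radial lines
#' scale with the local wall radius, so the mapped computational domain is
#' rectangular. Optional near-wall clustering uses a smooth tanh face
#' mapping (self-similar under refinement); `growth_rate` is the approximate
#' adjacent-spacing ratio in the wall layer at the default resolution
#' (1 gives a uniform radial grid).
#'
#' @param spec A [stenosed_vessel_spec()].
#' @param n_axial Number of axial cells, >= 16.
#' @param n_radial Number of radial cells, >= 8.
#' @param growth_rate Near-wall clustering growth rate, >= 1 (default 1.2).
#' @return Object of class `axisym_grid` with face/center coordinates, wall
#'   radius and slope at faces and centers, and cell cross-section areas.
#' @export
build_grid <- function(spec, n_axial = 96, n_radial = 24,
                       growth_rate = 1.2) {
  stopifnot(inherits(spec, "stenosed_vessel_spec"))
  if (n_axial < 16 || n_radial < 8) {
    stop("resolution below minimum (n_axial >= 16, n_radial >= 8)")
  }
  if (growth_rate < 1) stop("growth_rate must be >= 1")
  nz <- as.integer(n_axial); nr <- as.integer(n_radial)
  zf <- seq(0, spec$length, length.out = nz + 1L)
  zc <- (zf[-1] + zf[-(nz + 1L)]) / 2
  s <- seq(0, 1, length.out = nr + 1L)
  beta <- 2.2 * log(growth_rate) / log(1.2)
  # tanh face mapping, fine at the wall (eta = 1), coarse at the axis
  ef <- if (beta < 1e-10) s else tanh(beta * s) / tanh(beta)
  ef[1] <- 0; ef[nr + 1L] <- 1
  ec <- (ef[-1] + ef[-(nr + 1L)]) / 2
  g <- list(
    spec = spec, nz = nz, nr = nr,
    zf = zf, zc = zc, dz = diff(zf),
    ef = ef, ec = ec, def = diff(ef),
    Rf = wall_radius(spec, zf), Rc = wall_radius(spec, zc),
    Rpf = wall_radius_deriv(spec, zf), Rpc = wall_radius_deriv(spec, zc)
  )
  # annular cross-section area of cell ring j at axial face i:
  # pi R^2 (ef[j+1]^2 - ef[j]^2); partition of the disc is exact.
  g$ring_frac <- ef[-1]^2 - ef[-(nr + 1L)]^2
  structure(g, class = "axisym_grid")
}

#' Severity recovered from a built grid
#'
#' `1 - (min wall radius / inlet radius)^2`; equals the spec severity when an
#' axial node lies at the stenosis center.
#'
#' @param grid An [build_grid()] result.
#' @return Dimensionless area severity.
#' @export
grid_severity <- function(grid) {
  stopifnot(inherits(grid, "axisym_grid"))
  1 - (min(grid$Rf) / grid$spec$inlet_radius)^2
}
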