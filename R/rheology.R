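#' Carreau-Yasuda rheology parameters
#'
#' Container for the constants of the Carreau-Yasuda shear-thinning
#' viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + \frac{\mu_0 - \mu_\infty}
#'   {\left(1 + (\lambda\dot\gamma)^a\right)^{(1-n)/a}}}
#' with the standard whole-blood fit as defaults: zero-shear viscosity
#' \eqn{\mu_0 = 0.056} Pa s, infinite-shear viscosity
#' \eqn{\mu_\infty = 0.0035} Pa s, time constant \eqn{\lambda = 3.313} s and
#' power-law index \eqn{n = 0.3568}. The Yasuda transition exponent defaults
#' to \eqn{a = 2}, which reduces the law to the classical Carreau model
#' consistent with those four constants.
#'
#' @param mu_zero Zero-shear viscosity, Pa s.
#' @param mu_inf Infinite-shear viscosity, Pa s. Must satisfy
#'   `mu_zero > mu_inf > 0`.
#' @param lambda_time Relaxation time constant, s.
#' @param n_index Power-law index, dimensionless, in (0, 1).
#' @param a_exponent Yasuda transition exponent, dimensionless, > 0.
#' @return An object of class `cy_params`.
#' @seealso [apparent_viscosity()], [newtonian_viscosity()]
#' @examples
#' p <- cy_params()
#' apparent_viscosity(p, 0)      # 0.056
#' apparent_viscosity(p, 1e9)    # ~0.0035
#' @export
cy_params <- function(mu_zero = 0.056, mu_inf = 0.0035,
                      lambda_time = 3.313, n_index = 0.3568,
                      a_exponent = 2) {
  stopifnot(
    is.numeric(mu_zero), is.numeric(mu_inf), is.numeric(lambda_time),
    is.numeric(n_index), is.numeric(a_exponent),
    mu_inf > 0, mu_zero >= mu_inf,
    lambda_time > 0, n_index > 0, n_index < 1, a_exponent > 0
  )
  structure(
    list(mu_zero = mu_zero, mu_inf = mu_inf, lambda_time = lambda_time,
         n_index = n_index, a_exponent = a_exponent),
    class = "cy_params"
  )
}

#' Constant-viscosity (Newtonian) marker
#'
#' Degenerate rheology used for validation oracles (Poiseuille, Womersley)
#' and for Newtonian bounding runs.
#'
#' @param mu Dynamic viscosity, Pa s.
#' @return An object of class `newtonian_viscosity`.
#' @export
newtonian_viscosity <- function(mu = 0.0035) {
  stopifnot(is.numeric(mu), mu > 0)
  structure(list(mu = mu), class = "newtonian_viscosity")
}

#' Blood material properties
#'
#' @param density Mass density, kg/m^3 (whole blood: 1060).
#' @param rheology A [cy_params()] or [newtonian_viscosity()] object.
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1060, rheology = cy_params()) {
  stopifnot(is.numeric(density), density > 0,
            inherits(rheology, c("cy_params", "newtonian_viscosity")))
  structure(list(density = density, rheology = rheology),
            class = "blood_properties")
}

#' Apparent viscosity of a generalized Newtonian fluid
#'
#' Evaluates the shear-dependent viscosity at the given shear-rate
#' magnitude(s). For `cy_params` this is the Carreau-Yasuda law; for
#' `newtonian_viscosity` it returns the constant.
#'
#' @param params A [cy_params()] or [newtonian_viscosity()] object.
#' @param shear_rate Nonnegative shear-rate magnitude(s), 1/s. Callers must
#'   pass the invariant magnitude (see [shear_rate_magnitude()]); negative
#'   values are a domain error.
#' @return Viscosity value(s), Pa s, same length as `shear_rate`. Strictly
#'   within (`mu_inf`, `mu_zero`] for the Carreau-Yasuda law.
#' @export
apparent_viscosity <- function(params, shear_rate) {
  UseMethod("apparent_viscosity")
}

#' @export
apparent_viscosity.cy_params <- function(params, shear_rate) {
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0)) {
    stop("shear_rate must be finite and nonnegative")
  }
  p <- params
  p$mu_inf + (p$mu_zero - p$mu_inf) /
    (1 + (p$lambda_time * shear_rate)^p$a_exponent)^((1 - p$n_index) / p$a_exponent)
}

#' @export
apparent_viscosity.newtonian_viscosity <- function(params, shear_rate) {
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0)) {
    stop("shear_rate must be finite and nonnegative")
  }
  rep_len(params$mu, length(shear_rate))
}

#' Frame-invariant shear-rate magnitude
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\,D\!:\!D}} from a velocity-gradient
#' tensor, where \eqn{D = (\nabla v + \nabla v^T)/2} is the rate-of-deformation
#' tensor. This is the second-invariant magnitude consumed by the
#' Carreau-Yasuda law; it is invariant under rotations of the frame and
#' vanishes for rigid-body motion. For simple shear with
#' \eqn{\partial u/\partial y = k} it returns `k`.
#'
#' @param grad_v A 2x2 or 3x3 numeric matrix of velocity-gradient components
#'   (`grad_v[i, j]` = \eqn{\partial u_i/\partial x_j}), 1/s.
#' @return Nonnegative scalar shear rate, 1/s.
#' @export
shear_rate_magnitude <- function(grad_v) {
  stopifnot(is.matrix(grad_v), nrow(grad_v) == ncol(grad_v),
            nrow(grad_v) %in% c(2L, 3L))
  if (any(!is.finite(grad_v))) stop("grad_v entries must be finite")
  d <- (grad_v + t(grad_v)) / 2
  sqrt(2 * sum(d * d))
}
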