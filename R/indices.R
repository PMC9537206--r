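# Periodic trapezoid time integral over one cycle. On the uniform grid
# t_k = k T/n the wrapped trapezoid rule reduces to dt * sum(x); kept as a
# named helper so the quadrature convention lives in one place.
periodic_integral <- function(x, period) {
  (period / length(x)) * sum(x)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\vec\tau_w|\,dt}
#' computed per wall position by the composite trapezoid rule with periodic
#' closure (the last interval wraps to the first sample).
#'
#' @param series A [wall_traction_series()].
#' @return Numeric vector of TAWSS values, Pa, one per wall position.
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wall_traction_series"))
  mag <- sqrt(apply(series$tau^2, c(1, 2), sum))
  apply(mag, 1, function(m) periodic_integral(m, series$period)) /
    series$period
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{OSI = \frac12\left(1 -
#'   \frac{\left|\int_0^T \vec\tau_w\,dt\right|}
#'        {\int_0^T |\vec\tau_w|\,dt}\right)}
#' with the same periodic trapezoid quadrature as [tawss()]. The result is
#' clamped to `[0, 0.5]` against round-off; positions with an identically
#' zero traction magnitude integral return 0 by convention. OSI is 0 for a
#' traction vector constant in time and 0.5 for any zero-mean pattern
#' (reversing or rotating).
#'
#' @param series A [wall_traction_series()].
#' @return Numeric vector of OSI values, dimensionless, one per position.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wall_traction_series"))
  np <- length(series$position)
  mag <- sqrt(apply(series$tau^2, c(1, 2), sum))
  denom <- apply(mag, 1, function(m) periodic_integral(m, series$period))
  nc <- dim(series$tau)[3]
  int_vec <- sapply(seq_len(nc), function(c_) {
    apply(series$tau[, , c_, drop = FALSE], 1,
          function(x) periodic_integral(as.numeric(x), series$period))
  })
  int_vec <- matrix(int_vec, nrow = np)
  num <- sqrt(rowSums(int_vec^2))
  out <- numeric(np)
  ok <- denom > 0
  out[ok] <- 0.5 * (1 - num[ok] / denom[ok])
  pmin(pmax(out, 0), 0.5)
}

#' Relative residence time (RRT)
#'
#' \deqn{RRT = \frac{1}{(1 - 2\,OSI) \cdot TAWSS}}
#' RRT diverges as OSI approaches 0.5 (purely oscillatory shear) or TAWSS
#' approaches 0. Positions with `(1 - 2 OSI) < epsilon` are flagged singular
#' and reported as the capped value `1 / (epsilon * TAWSS)`; positions with
#' `TAWSS = 0` are flagged and reported as `Inf`. The flag keeps tabular
#' outputs finite and lets downstream summaries exclude singular wall zones
#' explicitly (they are the high-residence-time zones of interest).
#'
#' @param osi_values OSI per position, in `[0, 0.5]`.
#' @param tawss_values TAWSS per position, Pa, nonnegative.
#' @param epsilon Singularity cap on `(1 - 2 OSI)`, dimensionless, > 0.
#' @return A data frame with columns `rrt` (1/Pa) and `flag` (logical,
#'   TRUE where capped/singular).
#' @export
rrt <- function(osi_values, tawss_values, epsilon = 1e-3) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("epsilon must be a positive scalar")
  }
  stopifnot(length(osi_values) == length(tawss_values),
            all(osi_values >= 0), all(osi_values <= 0.5),
            all(tawss_values >= 0))
  dir_fac <- 1 - 2 * osi_values
  flag <- dir_fac < epsilon | tawss_values == 0
  val <- numeric(length(osi_values))
  ok <- !flag
  val[ok] <- 1 / (dir_fac[ok] * tawss_values[ok])
  capped <- flag & tawss_values > 0
  val[capped] <- 1 / (epsilon * tawss_values[capped])
  val[flag & tawss_values == 0] <- Inf
  data.frame(rrt = val, flag = flag)
}

#' Full wall-index profile
#'
#' Composes [tawss()], [osi()] and [rrt()] into a per-position table.
#'
#' @param series A [wall_traction_series()].
#' @param epsilon RRT singularity cap, see [rrt()].
#' @return Object of class `index_profile`: a data frame with columns
#'   `position` (m), `tawss` (Pa), `osi`, `rrt` (1/Pa), `rrt_flag`.
#' @export
index_profile <- function(series, epsilon = 1e-3) {
  ta <- tawss(series)
  os <- osi(series)
  rr <- rrt(os, ta, epsilon)
  structure(
    data.frame(position = series$position, tawss = ta, osi = os,
               rrt = rr$rrt, rrt_flag = rr$flag),
    class = c("index_profile", "data.frame")
  )
}

#' Index-profile CSV output
#'
#' Columns `position_m`, `tawss_Pa`, `osi`, `rrt_inv_Pa`, `rrt_flag`.
#'
#' @param profile An [index_profile()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
indices_to_csv <- function(profile, path) {
  stopifnot(inherits(profile, "index_profile"))
  df <- data.frame(position_m = profile$position,
                   tawss_Pa = profile$tawss,
                   osi = profile$osi,
                   rrt_inv_Pa = profile$rrt,
                   rrt_flag = as.integer(profile$rrt_flag))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
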