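# Discrete operators for the staggered axisymmetric solver.
#
# Layout (mapped coordinates zeta = z, eta = r / R(z)):
#   p  at cell centers            (zc[i], ec[j])   i = 1..nz, j = 1..nr
#   u  (axial velocity) at faces  (zf[i], ec[j])   i = 1..nz+1, j = 1..nr
#   v  (radial velocity) at faces (zc[i], ef[j])   i = 1..nz,   j = 1..nr+1
#
# The divergence D is the exact finite-volume net volume flux of each
# annular cell in PHYSICAL space (slanted eta-faces carry a u-component when
# the wall slopes). The pressure gradient G is the mapped-coordinate physical
# gradient at each velocity point, with zero rows at Dirichlet velocity DOFs
# and an affine part for the Dirichlet outlet pressure. The projection
# Poisson operator is assembled as the sparse product L = D %*% G, so the
# post-projection discrete divergence vanishes to linear-solver precision by
# construction, whatever the truncation order of D and G.

iu_idx <- function(i, j, nz) (j - 1L) * (nz + 1L) + i
iv_idx <- function(i, j, nz) (j - 1L) * nz + i
ip_idx <- function(i, j, nz) (j - 1L) * nz + i

#' Precomputed solver operators for a grid
#'
#' Builds the sparse divergence and pressure-gradient operators and the
#' LU-factored projection Poisson matrix for an [build_grid()] grid. Called
#' once per grid by [run_simulation()]; exposed so that [advance_step()] can
#' be driven directly in validation studies.
#'
#' @param grid An [build_grid()] grid.
#' @return An opaque list of class `flow_operators`.
#' @export
build_operators <- function(grid) {
  stopifnot(inherits(grid, "axisym_grid"))
  nz <- grid$nz; nr <- grid$nr
  Nu <- (nz + 1L) * nr; Nv <- nz * (nr + 1L); Np <- nz * nr
  ef <- grid$ef; ec <- grid$ec; zf <- grid$zf; zc <- grid$zc
  dz <- grid$dz; Rf <- grid$Rf; Rc <- grid$Rc
  Rpc <- grid$Rpc; Rpf <- grid$Rpf

  ## ---- divergence D : (u, v) -> net volume flux per cell --------------
  II <- rep(seq_len(nz), times = nr)
  JJ <- rep(seq_len(nr), each = nz)
  rows <- ip_idx(II, JJ, nz)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(r, c, x) {
    keep <- x != 0
    ti <<- c(ti, r[keep]); tj <<- c(tj, c[keep]); tx <<- c(tx, x[keep])
  }
  # east / west vertical faces
  AE <- pi * Rf[II + 1L]^2 * grid$ring_frac[JJ]
  AW <- pi * Rf[II]^2 * grid$ring_frac[JJ]
  add(rows, iu_idx(II + 1L, JJ, nz), AE)
  add(rows, iu_idx(II, JJ, nz), -AW)
  # north slanted face at ef[j+1] (skip wall j = nr: no-slip rigid => 0 flux)
  sel <- JJ < nr
  e <- ef[JJ + 1L]
  coefN <- 2 * pi * e * Rc[II] * dz[II]
  add(rows[sel], Nu + iv_idx(II, JJ + 1L, nz)[sel], coefN[sel])
  cu <- -coefN * e * Rpc[II] / 4
  for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    add(rows[sel], iu_idx(II + off[1], JJ + off[2], nz)[sel], cu[sel])
  }
  # south slanted face at ef[j] (skip axis j = 1: zero radius)
  sel <- JJ > 1L
  e <- ef[JJ]
  coefS <- 2 * pi * e * Rc[II] * dz[II]
  add(rows[sel], Nu + iv_idx(II, JJ, nz)[sel], -coefS[sel])
  cu <- coefS * e * Rpc[II] / 4
  for (off in list(c(0L, -1L), c(1L, -1L), c(0L, 0L), c(1L, 0L))) {
    add(rows[sel], iu_idx(II + off[1], JJ + off[2], nz)[sel], cu[sel])
  }
  D <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(Np, Nu + Nv))

  ## ---- gradient G : p (+ outlet value) -> physical grad at (u, v) -----
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  g_out <- numeric(Nu + Nv)
  # helper: eta-derivative stencil of p at center column j (one-sided edges)
  deta_cols <- function(j) {
    if (j == 1L) list(jm = 1L, jp = 2L, d = ec[2] - ec[1])
    else if (j == nr) list(jm = nr - 1L, jp = nr, d = ec[nr] - ec[nr - 1L])
    else list(jm = j - 1L, jp = j + 1L, d = ec[j + 1L] - ec[j - 1L])
  }
  # interior u rows i = 2..nz
  for (j in seq_len(nr)) {
    st <- deta_cols(j)
    for (i in 2:nz) {
      r <- iu_idx(i, j, nz)
      dzc <- zc[i] - zc[i - 1L]
      add(r, ip_idx(i, j, nz), 1 / dzc)
      add(r, ip_idx(i - 1L, j, nz), -1 / dzc)
      s_u <- ec[j] * Rpf[i] / Rf[i]
      if (s_u != 0) {
        # average of the eta-derivatives in the two adjacent cells
        for (ii in c(i - 1L, i)) {
          add(r, ip_idx(ii, st$jp, nz), -s_u * 0.5 / st$d)
          add(r, ip_idx(ii, st$jm, nz), s_u * 0.5 / st$d)
        }
      }
    }
    # outlet u row i = nz + 1 : one-sided towards the Dirichlet face value
    r <- iu_idx(nz + 1L, j, nz)
    dzo <- zf[nz + 1L] - zc[nz]
    add(r, ip_idx(nz, j, nz), -1 / dzo)
    g_out[r] <- 1 / dzo
    s_u <- ec[j] * Rpf[nz + 1L] / Rf[nz + 1L]
    if (s_u != 0) {
      add(r, ip_idx(nz, st$jp, nz), -s_u / st$d)
      add(r, ip_idx(nz, st$jm, nz), s_u / st$d)
    }
  }
  # interior v rows j = 2..nr
  for (j in 2:nr) {
    dec <- ec[j] - ec[j - 1L]
    for (i in seq_len(nz)) {
      r <- Nu + iv_idx(i, j, nz)
      add(r, ip_idx(i, j, nz), 1 / (dec * Rc[i]))
      add(r, ip_idx(i, j - 1L, nz), -1 / (dec * Rc[i]))
    }
  }
  G <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(Nu + Nv, Np))

  L <- D %*% G
  La <- as.numeric(D %*% g_out)
  structure(
    list(nz = nz, nr = nr, Nu = Nu, Nv = Nv, Np = Np,
         D = D, G = G, g_out = g_out, La = La,
         L_lu = Matrix::lu(L)),
    class = "flow_operators"
  )
}

# physical pressure gradient at all velocity DOFs (vector length Nu + Nv)
apply_gradient <- function(ops, p, p_out) {
  as.numeric(ops$G %*% as.numeric(p)) + ops$g_out * p_out
}

# exact-divergence projection: returns corrected fields and pressure increment
project_velocity <- function(ops, ustar, vstar, c_proj, phi_out) {
  w <- c(as.numeric(ustar), as.numeric(vstar))
  rhs <- as.numeric(ops$D %*% w) / c_proj - ops$La * phi_out
  phi <- as.numeric(Matrix::solve(ops$L_lu, rhs))
  w <- w - c_proj * (as.numeric(ops$G %*% phi) + ops$g_out * phi_out)
  nz <- ops$nz; nr <- ops$nr
  list(u = matrix(w[seq_len(ops$Nu)], nz + 1L, nr),
       v = matrix(w[ops$Nu + seq_len(ops$Nv)], nz, nr + 1L),
       phi = matrix(phi, nz, nr),
       div = as.numeric(ops$D %*% w))
}

# shear-rate magnitude field at cell centers from staggered velocities
shear_rate_field <- function(grid, u, v) {
  nz <- grid$nz; nr <- grid$nr
  ec <- grid$ec; Rc <- grid$Rc; Rpc <- grid$Rpc
  uc <- (u[-1, , drop = FALSE] + u[-(nz + 1L), , drop = FALSE]) / 2
  vc <- (v[, -1, drop = FALSE] + v[, -(nr + 1L), drop = FALSE]) / 2
  dz <- grid$dz[1]
  u_z <- (u[-1, , drop = FALSE] - u[-(nz + 1L), , drop = FALSE]) / dz
  # eta-derivatives at centers (central; one-sided at edges, wall uses u=0)
  u_e <- matrix(0, nz, nr); v_e <- matrix(0, nz, nr)
  if (nr > 2) {
    d <- rep(grid$ec[3:nr] - grid$ec[1:(nr - 2)], each = nz)
    u_e[, 2:(nr - 1)] <- (uc[, 3:nr] - uc[, 1:(nr - 2)]) / d
  }
  u_e[, 1] <- (uc[, 2] - uc[, 1]) / (ec[2] - ec[1])
  u_e[, nr] <- (0 - uc[, nr - 1]) / (1 - ec[nr - 1])
  v_e <- (v[, -1, drop = FALSE] - v[, -(nr + 1L), drop = FALSE]) /
    matrix(grid$def, nz, nr, byrow = TRUE)
  # zeta-derivative of v at centers (ghosts: 0 at inlet, zero-grad at outlet)
  v_z <- matrix(0, nz, nr)
  if (nz > 2) v_z[2:(nz - 1), ] <- (vc[3:nz, ] - vc[1:(nz - 2), ]) / (2 * dz)
  v_z[1, ] <- (vc[2, ] - 0) / (2 * dz)
  v_z[nz, ] <- (vc[nz, ] - vc[nz - 1, ]) / dz
  ecm <- matrix(ec, nz, nr, byrow = TRUE)
  Rcm <- matrix(Rc, nz, nr)
  slope <- matrix(Rpc / Rc, nz, nr) * ecm
  dudz <- u_z - slope * u_e
  dudr <- u_e / Rcm
  dvdz <- v_z - slope * v_e
  dvdr <- v_e / Rcm
  hoop <- vc / (ecm * Rcm)
  sqrt(pmax(2 * (dudz^2 + dvdr^2 + hoop^2) + (dudr + dvdz)^2, 0))
}

# viscosity at centers, corners (zf x ef) and v-points (zc x ef);
# mu_c_override supports under-relaxed Picard updates
viscosity_fields <- function(grid, props, u, v, mu_c_override = NULL) {
  if (is.null(mu_c_override)) {
    gam <- shear_rate_field(grid, u, v)
    mu_c <- matrix(apparent_viscosity(props$rheology, as.numeric(gam)),
                   grid$nz, grid$nr)
  } else {
    gam <- NULL
    mu_c <- mu_c_override
  }
  nz <- grid$nz; nr <- grid$nr
  pad <- mu_c[c(1, seq_len(nz), nz), c(1, seq_len(nr), nr)]
  mu_corner <- 0.25 * (pad[1:(nz + 1), 1:(nr + 1)] +
                       pad[2:(nz + 2), 1:(nr + 1)] +
                       pad[1:(nz + 1), 2:(nr + 2)] +
                       pad[2:(nz + 2), 2:(nr + 2)])
  mu_vp <- 0.5 * (mu_c[, c(1, seq_len(nr))] + mu_c[, c(seq_len(nr), nr)])
  list(mu_c = mu_c, mu_corner = mu_corner, mu_vp = mu_vp, gamma = gam)
}

# assemble and solve the u-momentum system (implicit upwind + diffusion)
solve_momentum_u <- function(grid, rho, at_c, u_lag, v_lag, mus, uhat,
                             gp_u, u_in) {
  nz <- grid$nz; nr <- grid$nr
  ec <- grid$ec; ef <- grid$ef; def <- grid$def
  Rf <- grid$Rf; Rpf <- grid$Rpf
  dz0 <- grid$dz[1]
  Nu <- (nz + 1L) * nr
  II <- rep(2:nz, times = nr)
  JJ <- rep(seq_len(nr), each = nz - 1L)
  rows <- iu_idx(II, JJ, nz)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(r, c, x) {
    ti <<- c(ti, r); tj <<- c(tj, c); tx <<- c(tx, x)
  }
  diagc <- rep(at_c, length(rows))
  # --- advection, zeta (implicit first-order upwind) ---
  a_z <- u_lag[cbind(II, JJ)]
  vbar <- 0.25 * (v_lag[cbind(II - 1L, JJ)] + v_lag[cbind(II - 1L, JJ + 1L)] +
                  v_lag[cbind(II, JJ)] + v_lag[cbind(II, JJ + 1L)])
  pos <- a_z >= 0
  cz <- rho * a_z / dz0
  diagc <- diagc + ifelse(pos, cz, -cz)
  add(rows[pos], iu_idx(II - 1L, JJ, nz)[pos], -cz[pos])
  add(rows[!pos], iu_idx(II + 1L, JJ, nz)[!pos], cz[!pos])
  # --- advection, eta ---
  a_e <- (vbar - a_z * ec[JJ] * Rpf[II]) / Rf[II]
  ce <- rho * a_e
  up <- a_e >= 0
  sel <- up & JJ > 1L          # backward difference (axis-symmetric: 0 at j=1)
  dm <- ec[pmax(JJ, 2L)] - ec[pmax(JJ - 1L, 1L)]
  diagc[sel] <- diagc[sel] + ce[sel] / dm[sel]
  add(rows[sel], iu_idx(II, JJ - 1L, nz)[sel], -(ce / dm)[sel])
  sel <- !up & JJ < nr         # forward difference
  dp <- ec[pmin(JJ + 1L, nr)] - ec[JJ]
  diagc[sel] <- diagc[sel] - ce[sel] / dp[sel]
  add(rows[sel], iu_idx(II, JJ + 1L, nz)[sel], (ce / dp)[sel])
  sel <- !up & JJ == nr        # forward to the no-slip wall value 0
  dw <- 1 - ec[nr]
  diagc[sel] <- diagc[sel] - ce[sel] / dw
  # --- radial diffusion (1/(eta R^2)) d_eta(eta mu d_eta u) ---
  # wall flux uses a one-sided quadratic through the two outermost rings and
  # the no-slip wall value (second order; exact for parabolic profiles)
  denom <- ec[JJ] * def[JJ] * Rf[II]^2
  dpt <- ifelse(JJ < nr, ec[pmin(JJ + 1L, nr)] - ec[JJ], 1 - ec[nr])
  cp <- ef[JJ + 1L] * mus$mu_corner[cbind(II, JJ + 1L)] / dpt / denom
  dmt <- ifelse(JJ > 1L, ec[JJ] - ec[pmax(JJ - 1L, 1L)], 1)
  cm <- ef[JJ] * mus$mu_corner[cbind(II, JJ)] / dmt / denom
  xa <- 1 - ec[nr]; xb <- 1 - ec[nr - 1L]
  wa <- xb / (xa * (xb - xa)); wb <- -xa / (xb * (xb - xa))
  atw <- JJ == nr
  mu_w <- mus$mu_corner[cbind(II, rep(nr + 1L, length(II)))]
  cp[atw] <- 0
  diagc <- diagc + cp + cm
  diagc[atw] <- diagc[atw] + (mu_w * wa / denom)[atw]
  add(rows[atw], iu_idx(II, JJ - 1L, nz)[atw], (mu_w * wb / denom)[atw])
  sel <- JJ < nr
  add(rows[sel], iu_idx(II, JJ + 1L, nz)[sel], -cp[sel])
  sel <- JJ > 1L
  add(rows[sel], iu_idx(II, JJ - 1L, nz)[sel], -cm[sel])
  # --- axial diffusion d_z(mu d_z u) ---
  me <- mus$mu_c[cbind(II, JJ)] / dz0^2
  mw <- mus$mu_c[cbind(II - 1L, JJ)] / dz0^2
  diagc <- diagc + me + mw
  add(rows, iu_idx(II + 1L, JJ, nz), -me)
  add(rows, iu_idx(II - 1L, JJ, nz), -mw)
  # --- diagonal and boundary rows ---
  add(rows, rows, diagc)
  jb <- seq_len(nr)
  rin <- iu_idx(rep(1L, nr), jb, nz)
  add(rin, rin, rep(1, nr))
  rout <- iu_idx(rep(nz + 1L, nr), jb, nz)
  add(rout, rout, rep(1, nr))
  add(rout, iu_idx(rep(nz, nr), jb, nz), rep(-1, nr))
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(Nu, Nu))
  b <- numeric(Nu)
  b[rows] <- at_c * uhat[cbind(II, JJ)] - gp_u[rows]
  b[rin] <- u_in
  matrix(as.numeric(Matrix::solve(A, b)), nz + 1L, nr)
}

# assemble and solve the v-momentum system
solve_momentum_v <- function(grid, rho, at_c, u_lag, v_lag, mus, vhat,
                             gp_v) {
  nz <- grid$nz; nr <- grid$nr
  ec <- grid$ec; ef <- grid$ef; def <- grid$def
  zc <- grid$zc; zf <- grid$zf
  Rc <- grid$Rc; Rpc <- grid$Rpc
  dz0 <- grid$dz[1]
  Nv <- nz * (nr + 1L)
  II <- rep(seq_len(nz), times = nr - 1L)
  JJ <- rep(2:nr, each = nz)
  rows <- iv_idx(II, JJ, nz)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  add <- function(r, c, x) {
    ti <<- c(ti, r); tj <<- c(tj, c); tx <<- c(tx, x)
  }
  diagc <- rep(at_c, length(rows))
  # --- advection, zeta (inlet ghost v = 0; outlet zero-gradient) ---
  a_z <- 0.25 * (u_lag[cbind(II, JJ - 1L)] + u_lag[cbind(II, JJ)] +
                 u_lag[cbind(II + 1L, JJ - 1L)] + u_lag[cbind(II + 1L, JJ)])
  cz <- rho * a_z
  pos <- a_z >= 0
  dzm <- ifelse(II > 1L, zc[II] - zc[pmax(II - 1L, 1L)], zc[1] - zf[1])
  diagc[pos] <- diagc[pos] + (cz / dzm)[pos]
  sel <- pos & II > 1L
  add(rows[sel], iv_idx(II - 1L, JJ, nz)[sel], -(cz / dzm)[sel])
  sel <- !pos & II < nz
  dzp <- zc[pmin(II + 1L, nz)] - zc[II]
  diagc[sel] <- diagc[sel] - (cz / dzp)[sel]
  add(rows[sel], iv_idx(II + 1L, JJ, nz)[sel], (cz / dzp)[sel])
  # --- advection, eta (neighbours include Dirichlet rows at axis/wall) ---
  a_e <- (v_lag[cbind(II, JJ)] - a_z * ef[JJ] * Rpc[II]) / Rc[II]
  ce <- rho * a_e
  up <- a_e >= 0
  dem <- ef[JJ] - ef[JJ - 1L]
  dep <- ef[JJ + 1L] - ef[JJ]
  diagc[up] <- diagc[up] + (ce / dem)[up]
  add(rows[up], iv_idx(II, JJ - 1L, nz)[up], -(ce / dem)[up])
  diagc[!up] <- diagc[!up] - (ce / dep)[!up]
  add(rows[!up], iv_idx(II, JJ + 1L, nz)[!up], (ce / dep)[!up])
  # --- radial diffusion + hoop term ---
  denom <- ef[JJ] * (ec[JJ] - ec[JJ - 1L]) * Rc[II]^2
  gp_ <- ec[JJ] * mus$mu_c[cbind(II, JJ)] / def[JJ] / denom
  gm_ <- ec[JJ - 1L] * mus$mu_c[cbind(II, JJ - 1L)] / def[JJ - 1L] / denom
  diagc <- diagc + gp_ + gm_
  add(rows, iv_idx(II, JJ + 1L, nz), -gp_)
  add(rows, iv_idx(II, JJ - 1L, nz), -gm_)
  diagc <- diagc + mus$mu_vp[cbind(II, JJ)] / (ef[JJ] * Rc[II])^2
  # --- axial diffusion (inlet ghost v = 0; outlet zero-gradient) ---
  dzp <- ifelse(II < nz, zc[pmin(II + 1L, nz)] - zc[II], 1)
  me <- ifelse(II < nz, mus$mu_corner[cbind(II + 1L, JJ)] / dzp, 0) / dz0
  dzm <- ifelse(II > 1L, zc[II] - zc[pmax(II - 1L, 1L)], zc[1] - zf[1])
  mw <- mus$mu_corner[cbind(II, JJ)] / dzm / dz0
  diagc <- diagc + me + mw
  sel <- II < nz
  add(rows[sel], iv_idx(II + 1L, JJ, nz)[sel], -me[sel])
  sel <- II > 1L
  add(rows[sel], iv_idx(II - 1L, JJ, nz)[sel], -mw[sel])
  # --- diagonal and Dirichlet rows (axis j = 1, wall j = nr + 1) ---
  add(rows, rows, diagc)
  ib <- seq_len(nz)
  rax <- iv_idx(ib, rep(1L, nz), nz)
  rwl <- iv_idx(ib, rep(nr + 1L, nz), nz)
  add(c(rax, rwl), c(rax, rwl), rep(1, 2 * nz))
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(Nv, Nv))
  b <- numeric(Nv)
  b[rows] <- at_c * vhat[cbind(II, JJ)] - gp_v[rows]
  matrix(as.numeric(Matrix::solve(A, b)), nz, nr + 1L)
}
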