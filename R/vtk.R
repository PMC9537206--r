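# Legacy-VTK (ASCII) structured-grid output for inspection in ParaView.
# The axisymmetric half-plane is written as a (nz+1) x (nr+1) x 1 grid of
# (z, r, 0) points.

#' Write a grid (with optional point data) as legacy VTK
#'
#' @param grid An [build_grid()] grid.
#' @param path Output file path.
#' @param point_data Named list of `(nz+1) x (nr+1)` matrices of node values.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(grid, path, point_data = list()) {
  nz <- grid$nz; nr <- grid$nr
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "stenoflow axisymmetric grid", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz + 1L, nr + 1L),
               sprintf("POINTS %d double", (nz + 1L) * (nr + 1L))), con)
  for (j in seq_len(nr + 1L)) {
    r <- grid$ef[j] * grid$Rf
    writeLines(sprintf("%.9g %.9g 0", grid$zf, r), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", (nz + 1L) * (nr + 1L)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      m <- point_data[[nm]]
      for (j in seq_len(nr + 1L)) writeLines(sprintf("%.9g", m[, j]), con)
    }
  }
  invisible(path)
}

# interpolate staggered fields to grid nodes (zf x ef)
fields_at_nodes <- function(grid, u, v, p) {
  nz <- grid$nz; nr <- grid$nr
  un <- matrix(0, nz + 1L, nr + 1L)
  un[, 2:nr] <- (u[, 1:(nr - 1)] + u[, 2:nr]) / 2
  un[, 1] <- u[, 1]               # axis: symmetric
  un[, nr + 1L] <- 0              # wall: no slip
  vn <- matrix(0, nz + 1L, nr + 1L)
  vn[2:nz, ] <- (v[1:(nz - 1), ] + v[2:nz, ]) / 2
  vn[1, ] <- v[1, ]; vn[nz + 1L, ] <- v[nz, ]
  pn <- matrix(0, nz + 1L, nr + 1L)
  pc <- p[c(1, seq_len(nz), nz), c(1, seq_len(nr), nr)]
  pn <- 0.25 * (pc[1:(nz + 1), 1:(nr + 1)] + pc[2:(nz + 2), 1:(nr + 1)] +
                pc[1:(nz + 1), 2:(nr + 2)] + pc[2:(nz + 2), 2:(nr + 2)])
  list(u = un, v = vn, p = pn)
}

#' Dump final-cycle fields of a solution as legacy VTK files
#'
#' Writes `fields_c<cycle>_t<index>.vtk` files with axial velocity, radial
#' velocity and pressure as point data.
#'
#' @param solution A [run_simulation()] result.
#' @param dir Output directory.
#' @param every Write every n-th stored instant (default 10).
#' @param tag Optional filename tag inserted before the cycle index.
#' @return Paths written, invisibly.
#' @export
write_solution_vtk <- function(solution, dir, every = 10L, tag = NULL) {
  grid <- solution$grid
  keep <- which(solution$times >= solution$t_final0 - 1e-12)
  keep <- keep[seq(1, length(keep), by = every)]
  cyc <- solution$config$n_cycles
  paths <- character(0)
  for (k in seq_along(keep)) {
    st <- solution$states[[keep[k]]]
    nd <- fields_at_nodes(grid, st$u, st$v, st$p)
    fn <- if (is.null(tag)) {
      sprintf("fields_c%d_t%03d.vtk", cyc, k)
    } else {
      sprintf("fields_%s_c%d_t%03d.vtk", tag, cyc, k)
    }
    path <- file.path(dir, fn)
    write_vtk_grid(grid, path,
                   point_data = list(u_axial = nd$u, u_radial = nd$v,
                                     pressure = nd$p))
    paths <- c(paths, path)
  }
  invisible(paths)
}
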