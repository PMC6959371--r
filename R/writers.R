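#' Write fluid fields as a legacy-VTK structured-points file
#'
#' ASCII legacy VTK with density, pressure and velocity point data, one
#' point per lattice node.
#'
#' @param fluid list with `rho`, `ux`, `uy` matrices (e.g. a `fields`
#'   element of an `lbad_sim`, or a [make_fixture_flow()] state).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vtk_fields <- function(fluid, path) {
  Nx <- nrow(fluid$rho)
  Ny <- ncol(fluid$rho)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 2.0",
    "lbadhesion fields",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", Nx, Ny),
    "ORIGIN 0 0 0",
    "SPACING 1 1 1",
    sprintf("POINT_DATA %d", Nx * Ny),
    "SCALARS density double 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(format(as.vector(fluid$rho), digits = 10), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(fluid$rho) / 3, digits = 10), con)
  writeLines("VECTORS velocity double", con)
  writeLines(
    paste(format(as.vector(fluid$ux), digits = 10),
          format(as.vector(fluid$uy), digits = 10), "0"),
    con
  )
  invisible(path)
}

#' Write a trajectory record as CSV
#'
#' Normalized columns: `t u_max/H`, `y_min/H`, angle, `u_x/u_max`,
#' `Omega H/u_max`, active-bond fraction.
#'
#' @param sim an `lbad_sim` (or its trajectory tibble).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  traj <- if (inherits(sim, "lbad_sim")) sim$trajectory else sim
  out <- data.frame(
    t_umax_H = traj$t_conv,
    y_min_H = traj$y_min_H,
    theta = traj$theta,
    ux_umax = traj$ux_umax,
    omegaH_umax = traj$omega_norm,
    active_fraction = traj$n_active / traj$n_total
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a phase map as CSV (long format)
#'
#' @param map tibble from [sweep_phase_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phase_map_csv <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Write a bond-event log as CSV
#'
#' @param events data frame of events accumulated from the `"events"`
#'   attribute of [update_bonds()] sweeps (columns `step`, `element`,
#'   `event`, `y_l`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bond_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Boundary snapshot as CSV
#'
#' Element centroids, outward normals and per-element bond state of the
#' final configuration of a run.
#'
#' @param sim an `lbad_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(sim, path) {
  geo <- element_geometry(sim$markers)
  out <- data.frame(
    element = seq_len(nrow(geo$centroids)),
    x = geo$centroids[, 1], y = geo$centroids[, 2],
    nx = geo$normals[, 1], ny = geo$normals[, 2],
    length = geo$lengths,
    ligand = sim$ligand,
    bond_active = as.logical(sim$bond_active)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
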