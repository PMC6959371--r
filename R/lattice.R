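#' D2Q9 velocity set
#'
#' The nine discrete velocities, quadrature weights and speed of sound of
#' the two-dimensional D2Q9 lattice (dx = dt = 1).  Ordering: rest particle,
#' the four axis directions (east, north, west, south), then the four
#' diagonals (NE, NW, SW, SE).
#'
#' @return A list with `e` (9 x 2 integer matrix of lattice velocities),
#'   `w` (weights 4/9, 1/9, 1/36), `cs2` (= 1/3) and `cs` (= 1/sqrt(3)).
#' @export
#' @examples
#' vs <- lbm_velocity_set()
#' colSums(vs$w * vs$e)     # zero first moment
lbm_velocity_set <- function() {
  e <- cbind(
    c(0L, 1L, 0L, -1L, 0L, 1L, -1L, -1L, 1L),
    c(0L, 0L, 1L, 0L, -1L, 1L, 1L, -1L, -1L)
  )
  w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
  list(e = e, w = w, cs2 = 1 / 3, cs = 1 / sqrt(3))
}

#' Kinematic viscosity of the BGK lattice
#'
#' `nu = cs2 * (tau - 1/2)` in lattice units.
#'
#' @param tau relaxation time (lattice time units), must exceed 1/2.
#' @return kinematic viscosity in lattice units.
#' @export
lbm_viscosity <- function(tau) {
  if (any(tau <= 0.5)) stop("relaxation time tau must exceed 1/2")
  (tau - 0.5) / 3
}

as_u_matrix <- function(u, n) {
  if (is.null(dim(u))) {
    if (length(u) == 2L) u <- matrix(u, n, 2, byrow = TRUE)
    else stop("velocity must be a length-2 vector or an n x 2 matrix")
  }
  u
}

#' Maxwell-Boltzmann equilibrium populations
#'
#' Second-order truncated equilibrium
#' `w_i rho [1 + (e_i.u)/cs2 + (e_i.u)^2/(2 cs4) - u^2/(2 cs2)]`.
#'
#' @param rho density (positive scalar or vector).
#' @param u velocity, a length-2 vector or an `n x 2` matrix in lattice units.
#' @return an `n x 9` matrix of equilibrium populations.
#' @export
#' @examples
#' f <- equilibrium_populations(1, c(0.1, 0))
#' sum(f)                       # recovers rho = 1
equilibrium_populations <- function(rho, u) {
  n <- length(rho)
  u <- as_u_matrix(u, n)
  if (nrow(u) != n) stop("rho and u have incompatible sizes")
  if (any(!is.finite(rho)) || any(rho <= 0))
    stop("invalid state: density must be positive and finite")
  mach <- sqrt(rowSums(u^2)) * sqrt(3)
  if (any(mach > 0.1))
    warning("local Mach number above 0.1: equilibrium truncation degrades")
  cpp_equilibrium(rho, u[, 1], u[, 2])
}

#' Guo forcing contributions
#'
#' Second-order body-force contributions
#' `(1 - 1/(2 tau)) w_i [(e_i - u)/cs2 + (e_i.u)/cs4 e_i] . f_ib`.
#' Their zeroth moment vanishes and their first moment is
#' `(1 - 1/(2 tau)) f_ib`.
#'
#' @param u velocity (length-2 or `n x 2`).
#' @param f_ib body-force density (length-2 or `n x 2`), lattice units.
#' @param tau relaxation time, > 1/2.
#' @return an `n x 9` matrix of forcing contributions.
#' @export
guo_forcing_term <- function(u, f_ib, tau) {
  if (tau <= 0.5) stop("relaxation time tau must exceed 1/2")
  n <- max(
    if (is.null(dim(u))) 1L else nrow(u),
    if (is.null(dim(f_ib))) 1L else nrow(f_ib)
  )
  u <- as_u_matrix(u, n)
  f_ib <- as_u_matrix(f_ib, n)
  cpp_guo_forcing(u[, 1], u[, 2], f_ib[, 1], f_ib[, 2], tau)
}

check_populations <- function(f) {
  if (length(dim(f)) != 3L || dim(f)[3] != 9L)
    stop("populations must be an Nx x Ny x 9 array")
}

#' Initialize populations at local equilibrium
#'
#' @param rho density matrix (`Nx x Ny`).
#' @param ux,uy velocity component matrices.
#' @return an `Nx x Ny x 9` population array.
#' @export
lbm_init_populations <- function(rho, ux, uy) {
  feq <- cpp_equilibrium(as.vector(rho), as.vector(ux), as.vector(uy))
  array(feq, dim = c(nrow(rho), ncol(rho), 9L))
}

#' BGK collide-and-stream update
#'
#' One lattice Boltzmann step: BGK relaxation toward the local equilibrium
#' (with optional Guo forcing) followed by propagation along the discrete
#' velocities.  The x-faces are periodic; with `walls = TRUE` the y-faces
#' are treated as wall rows whose unknown incoming populations are zeroed,
#' to be reconstructed by [apply_wall_velocity_bc()]; with `walls = FALSE`
#' the domain is fully periodic.
#'
#' @param f population array `Nx x Ny x 9`.
#' @param tau relaxation time, > 1/2.
#' @param forcing optional list with `gx`, `gy` body-force density matrices.
#' @param walls logical: treat the y-faces as walls (default) or as periodic.
#' @return updated population array.
#' @export
collide_and_stream <- function(f, tau, forcing = NULL, walls = TRUE) {
  check_populations(f)
  if (tau <= 0.5) stop("relaxation time tau must exceed 1/2")
  d <- dim(f)
  gx <- gy <- NULL
  if (!is.null(forcing)) {
    gx <- as.vector(forcing$gx)
    gy <- as.vector(forcing$gy)
  }
  if (any(!is.finite(f)))
    stop("instability: non-finite populations before collision")
  out <- cpp_collide_stream(as.vector(f), d[1], d[2], tau, gx, gy, !walls)
  array(out, dim = d)
}

#' Macroscopic moments of the populations
#'
#' Density `rho = sum_i f_i`, momentum `rho u = sum_i f_i e_i + dt/2 f_ib`
#' (the half-force correction of the Guo scheme) and pressure `p = cs2 rho`.
#'
#' @inheritParams collide_and_stream
#' @return list with matrices `rho`, `ux`, `uy`, `p`.
#' @export
compute_moments <- function(f, forcing = NULL) {
  check_populations(f)
  d <- dim(f)
  gx <- gy <- NULL
  if (!is.null(forcing)) {
    gx <- as.vector(forcing$gx)
    gy <- as.vector(forcing$gy)
  }
  m <- cpp_moments(as.vector(f), d[1], d[2], gx, gy)
  list(
    rho = matrix(m$rho, d[1], d[2]),
    ux = matrix(m$ux, d[1], d[2]),
    uy = matrix(m$uy, d[1], d[2]),
    p = matrix(m$rho / 3, d[1], d[2])
  )
}

#' Zou-He known-velocity wall closure
#'
#' Reconstructs the three unknown populations on a wall row so that the
#' row's moments recover exactly the prescribed tangential wall velocity
#' (zero wall-normal velocity).  The channel is x-periodic, so the wall
#' rows carry no corner nodes and no corner closure is needed.
#'
#' @param f population array `Nx x Ny x 9` (post-streaming).
#' @param wall `"bottom"` (row y = 1) or `"top"` (row y = Ny).
#' @param u_wall tangential wall velocity (scalar, lattice units).
#' @return population array with the wall row reconstructed.
#' @export
apply_wall_velocity_bc <- function(f, wall = c("bottom", "top"), u_wall = 0) {
  check_populations(f)
  wall <- match.arg(wall)
  if (length(u_wall) == 2L) {
    if (u_wall[2] != 0) stop("only tangential wall velocities are supported")
    u_wall <- u_wall[1]
  }
  d <- dim(f)
  if (wall == "bottom") {
    y <- 1L
    rho <- f[, y, 1] + f[, y, 2] + f[, y, 4] +
      2 * (f[, y, 5] + f[, y, 8] + f[, y, 9])
    f[, y, 3] <- f[, y, 5]
    f[, y, 6] <- f[, y, 8] - 0.5 * (f[, y, 2] - f[, y, 4]) +
      0.5 * rho * u_wall
    f[, y, 7] <- f[, y, 9] + 0.5 * (f[, y, 2] - f[, y, 4]) -
      0.5 * rho * u_wall
  } else {
    y <- d[2]
    rho <- f[, y, 1] + f[, y, 2] + f[, y, 4] +
      2 * (f[, y, 3] + f[, y, 6] + f[, y, 7])
    f[, y, 5] <- f[, y, 3]
    f[, y, 8] <- f[, y, 6] + 0.5 * (f[, y, 2] - f[, y, 4]) -
      0.5 * rho * u_wall
    f[, y, 9] <- f[, y, 7] - 0.5 * (f[, y, 2] - f[, y, 4]) +
      0.5 * rho * u_wall
  }
  f
}

#' Integrate a particle-free channel flow
#'
#' Fast path for benchmark flows (plane Couette, body-force Poiseuille):
#' repeated collide-stream sweeps with a uniform body force and Zou-He
#' walls, starting from rest unless initial populations are supplied.
#'
#' @param Nx,Ny grid size (Ny includes both wall rows; channel height is
#'   `Ny - 1` lattice units).
#' @param tau relaxation time.
#' @param nsteps number of lattice steps.
#' @param body_force uniform body-force density `c(gx, gy)`.
#' @param u_bottom,u_top tangential wall velocities.
#' @param f optional initial populations.
#' @return list with the final populations `f` and moments as in
#'   [compute_moments()].
#' @export
run_channel_flow <- function(Nx, Ny, tau, nsteps, body_force = c(0, 0),
                             u_bottom = 0, u_top = 0, f = NULL) {
  if (is.null(f)) {
    f <- lbm_init_populations(
      matrix(1, Nx, Ny), matrix(0, Nx, Ny), matrix(0, Nx, Ny)
    )
  }
  out <- cpp_run_channel(
    as.vector(f), Nx, Ny, tau, body_force[1], body_force[2],
    u_bottom, u_top, as.integer(nsteps)
  )
  f <- array(out, dim = c(Nx, Ny, 9L))
  forcing <- NULL
  if (any(body_force != 0)) {
    forcing <- list(
      gx = matrix(body_force[1], Nx, Ny),
      gy = matrix(body_force[2], Nx, Ny)
    )
  }
  c(list(f = f), compute_moments(f, forcing))
}
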