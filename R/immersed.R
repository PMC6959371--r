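#' Direct-forcing immersed-boundary body force
#'
#' Computes the Eulerian body-force density field that drives the fluid
#' velocity at the boundary elements toward the target (rigid-body) element
#' velocities: the velocity defect at each element centroid is turned into
#' a momentum correction and spread back to the grid with the transposed
#' MLS weights, scaled by the element length (one direct-forcing correction
#' per step).  Wall rows are excluded from the spreading so the Zou-He
#' closure stays exact.
#'
#' @param placed world-frame boundary from [place_boundary()].
#' @param fluid list with `ux`, `uy` (and optionally `rho`) matrices.
#' @param targets `n x 2` matrix of target element velocities.
#' @param walls logical; exclude wall rows from spreading (default TRUE).
#' @param support_radius MLS support radius.
#' @return list with body-force density matrices `gx`, `gy`.
#' @export
compute_ib_force <- function(placed, fluid, targets, walls = TRUE,
                             support_radius = 2.5) {
  Nx <- nrow(fluid$ux)
  Ny <- ncol(fluid$ux)
  gx <- matrix(0, Nx, Ny)
  gy <- matrix(0, Nx, Ny)
  uxv <- as.vector(fluid$ux)
  uyv <- as.vector(fluid$uy)
  for (k in seq_len(nrow(placed$centroids))) {
    st <- cpp_mls_stencil(
      placed$centroids[k, 1] %% Nx, placed$centroids[k, 2],
      Nx, Ny, support_radius, TRUE
    )
    uf <- sum(st$phi * uxv[st$idx])
    vf <- sum(st$phi * uyv[st$idx])
    Fx <- (targets[k, 1] - uf) * placed$lengths[k]
    Fy <- (targets[k, 2] - vf) * placed$lengths[k]
    keep <- rep(TRUE, length(st$idx))
    if (walls) {
      row <- (st$idx - 1L) %/% Nx
      keep <- row > 0L & row < (Ny - 1L)
    }
    gx[st$idx[keep]] <- gx[st$idx[keep]] + st$phi[keep] * Fx
    gy[st$idx[keep]] <- gy[st$idx[keep]] + st$phi[keep] * Fy
  }
  list(gx = gx, gy = gy)
}

#' Pressure and viscous loads on an immersed boundary
#'
#' Integrates the fluid traction over the boundary elements.  Pressure and
#' velocity gradients are evaluated by MLS at a probe placed along each
#' element's outward normal (default 1.2 spacings); the probe values are
#' assigned to the element centroid.  Probes that would leave the fluid
#' (elements facing a nearby wall) are clamped to remain inside.
#'
#' Pressure force: `F_p = sum_l (-p_l n_l) S_l`; viscous force:
#' `F_v = sum_l (tau_l . n_l) S_l` with the Newtonian deviatoric stress
#' `tau = mu (grad u + grad u^T)`; moment about the particle centroid from
#' the total traction.
#'
#' @param placed world-frame boundary from [place_boundary()].
#' @param fluid list with `rho`, `ux`, `uy` matrices.
#' @param nu kinematic viscosity (lattice units).
#' @param x_c particle centroid (moment reference point).
#' @param support_radius MLS support radius.
#' @return list with `pressure_force`, `viscous_force` (length-2 vectors)
#'   and scalar `moment`.
#' @export
evaluate_loads <- function(placed, fluid, nu, x_c, support_radius = 2.5) {
  Nx <- nrow(fluid$rho)
  Ny <- ncol(fluid$rho)
  rhov <- as.vector(fluid$rho)
  uxv <- as.vector(fluid$ux)
  uyv <- as.vector(fluid$uy)
  Fp <- c(0, 0)
  Fv <- c(0, 0)
  M <- 0
  for (k in seq_len(nrow(placed$centroids))) {
    px <- placed$probes[k, 1] %% Nx
    py <- min(max(placed$probes[k, 2], 0.1), Ny - 1.1)
    st <- cpp_mls_stencil(px, py, Nx, Ny, support_radius, TRUE)
    pr <- sum(st$phi * rhov[st$idx])
    dudx <- sum(st$dphi_dx * uxv[st$idx])
    dudy <- sum(st$dphi_dy * uxv[st$idx])
    dvdx <- sum(st$dphi_dx * uyv[st$idx])
    dvdy <- sum(st$dphi_dy * uyv[st$idx])
    p <- pr / 3
    mu <- nu * pr
    nl <- placed$normals[k, ]
    S <- placed$lengths[k]
    fp <- -p * nl * S
    tr <- c(
      2 * mu * dudx * nl[1] + mu * (dudy + dvdx) * nl[2],
      mu * (dudy + dvdx) * nl[1] + 2 * mu * dvdy * nl[2]
    ) * S
    Fp <- Fp + fp
    Fv <- Fv + tr
    r <- placed$centroids[k, ] - x_c
    tot <- fp + tr
    M <- M + r[1] * tot[2] - r[2] * tot[1]
  }
  list(pressure_force = Fp, viscous_force = Fv, moment = M)
}
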