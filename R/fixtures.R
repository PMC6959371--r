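#' Analytic fixture flow fields
#'
#' Prescribed fluid states on a grid, for exercising the MLS transfer,
#' load evaluation and adhesion code without running the solver: plane
#' Couette (`u_x = u_max y/H`), body-force Poiseuille
#' (`u_x = 4 u_max y (H - y)/H^2`) and a uniform pressure state at rest.
#'
#' @param kind `"couette"`, `"poiseuille"` or `"uniform"`.
#' @param Nx,Ny grid size (channel height `H = Ny - 1`).
#' @param u_max peak velocity (lattice units).
#' @param p0 uniform pressure for the `"uniform"` state (lattice units).
#' @return list with `rho`, `ux`, `uy`, `p` matrices.
#' @export
#' @examples
#' flo <- make_fixture_flow("couette", Nx = 16, Ny = 33, u_max = 0.02)
make_fixture_flow <- function(kind = c("couette", "poiseuille", "uniform"),
                              Nx, Ny, u_max = 0.01, p0 = 1 / 3) {
  kind <- match.arg(kind)
  H <- Ny - 1
  y <- matrix(rep(0:(Ny - 1), each = Nx), Nx, Ny)
  ux <- switch(kind,
    couette = u_max * y / H,
    poiseuille = 4 * u_max * y * (H - y) / H^2,
    uniform = matrix(0, Nx, Ny)
  )
  rho <- if (kind == "uniform") matrix(3 * p0, Nx, Ny) else matrix(1, Nx, Ny)
  list(rho = rho, ux = ux, uy = matrix(0, Nx, Ny), p = rho / 3)
}
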