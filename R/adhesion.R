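#' Adhesive-dynamics parameter set
#'
#' Assembles the ligand-receptor bond parameters in lattice units.  The
#' geometric scales come straight from the model definition: critical
#' bond-formation distance `y_cr = 6.8e-3 H`, equilibrium bond length
#' `y_cr,eq = 0.5 y_cr`, equilibrium spring constant `sigma* = 0.5 sigma`
#' (slip bonds).  The spring constant is non-dimensionalized by
#' `rho_ref nu^2 / H` and the Hamaker constant by `rho_ref H nu^2`.
#'
#' The absolute kinetic rates are tied to the biochemical affinity
#' `k_f / k_r0 = 8.5e3`.  Defaults follow declared closure rules (all
#' overridable):
#' \itemize{
#'   \item `k_r0 dt = 1e-4 (200/H_nodes)^2` — the reference unstressed
#'     rupture rate at the stock 200-node resolution, rescaled with the
#'     diffusive time unit so the physical rate is resolution-independent;
#'   \item `k_B T` such that the slip-bond exponent is 5 at full stretch
#'     `|y_l - y_cr,eq| = y_cr,eq` for `sigma = 2`: strain then dominates
#'     rupture, so a lone overloaded bond releases quickly while
#'     load-sharing bond clusters persist — the discrimination that
#'     separates detaching from adhering ligand densities;
#'   \item Hamaker constant from a contact-scale balance: the wall
#'     repulsion evaluated at the critical distance equals `hk_scale`
#'     times the pull of two fully stretched `sigma = 2` bonds, with the
#'     amplitude `hk_scale = 0.3` estimated against the near-critical
#'     separation band of the circular-particle runs (methods vignette).
#' }
#'
#' @param H channel height in lattice units.
#' @param nu kinematic viscosity in lattice units.
#' @param sigma dimensionless bond spring constant (1 = soft, 2 = rigid).
#' @param kf_kr0 biochemical affinity `k_f / k_r0`.
#' @param kr0_dt unstressed reverse rate per lattice step (NULL = rule).
#' @param kBT_lat thermal potential in lattice units (NULL = rule).
#' @param Hk_lat Hamaker constant in lattice units (NULL = rule).
#' @param hk_scale amplitude of the Hamaker closure rule.
#' @param y_cr_H critical bond-formation distance over H.
#' @param r_eq_lat equivalent particle radius (lattice units) entering the
#'   wall-repulsion law; defaults to the radius of the nominal-area
#'   particle, `sqrt(0.025/pi) H`.
#' @param H_nodes wall-normal node count (for the rate rescaling rule);
#'   defaults to `H + 1`.
#' @param rho0 reference density.
#' @return list of class `lbad_adhesion_params` with lattice-unit fields
#'   `sigma_lat`, `sigma_eq_lat`, `y_cr`, `y_eq`, `kf_dt`, `kr0_dt`,
#'   `kBT`, `Hk`, `r_eq`, plus the dimensionless inputs.
#' @export
adhesion_params <- function(H, nu, sigma = 2, kf_kr0 = 8.5e3,
                            kr0_dt = NULL, kBT_lat = NULL, Hk_lat = NULL,
                            hk_scale = 0.3, y_cr_H = 6.8e-3,
                            r_eq_lat = NULL, H_nodes = NULL, rho0 = 1) {
  if (is.null(H_nodes)) H_nodes <- H + 1
  y_cr <- y_cr_H * H
  y_eq <- 0.5 * y_cr
  sigma_lat <- sigma * rho0 * nu^2 / H
  if (is.null(kr0_dt)) kr0_dt <- 1e-4 * (200 / H_nodes)^2
  kf_dt <- kf_kr0 * kr0_dt
  if (is.null(kBT_lat)) {
    # exponent (sigma - sigma*) y_eq^2 / (2 kBT) = 5 at full stretch, sigma=2
    kBT_lat <- (2 - 1) * rho0 * nu^2 / H * y_eq^2 / 10
  }
  if (is.null(r_eq_lat)) r_eq_lat <- sqrt(0.025 / pi) * H
  if (is.null(Hk_lat)) {
    sigma2 <- 2 * rho0 * nu^2 / H
    f_bonds <- 2 * sigma2 * y_eq # two bonds stretched to y_cr, unit element
    Hk_lat <- hk_scale * f_bonds * 8 * sqrt(2) / sqrt(r_eq_lat / y_cr^5)
  }
  structure(list(
    sigma = sigma, sigma_lat = sigma_lat, sigma_eq_lat = 0.5 * sigma_lat,
    y_cr = y_cr, y_eq = y_eq, y_cr_H = y_cr_H,
    kf_kr0 = kf_kr0, kf_dt = kf_dt, kr0_dt = kr0_dt,
    kBT = kBT_lat, Hk = Hk_lat, r_eq = r_eq_lat,
    H = H, nu = nu, rho0 = rho0
  ), class = "lbad_adhesion_params")
}

#' Seed ligand molecules on the boundary elements
#'
#' Each surface element independently carries a ligand with probability
#' `rho_l` (uniform coverage; the wall is fully receptor-covered).
#'
#' @param n_elements number of surface elements (or an `lbad_boundary`).
#' @param rho_l ligand density in `[0, 1]`.
#' @param seed optional seed applied locally (the caller's RNG state is
#'   restored on exit); if NULL the current RNG stream is used.
#' @return logical vector: ligand present per element.
#' @export
seed_ligands <- function(n_elements, rho_l, seed = NULL) {
  if (inherits(n_elements, "lbad_boundary")) n_elements <- n_elements$n
  if (rho_l < 0 || rho_l > 1)
    stop("ligand density rho_l must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  runif(n_elements) < rho_l
}

#' Ligand-receptor spring bond force
#'
#' `f = sigma (y_l - y_cr,eq)` along the element-to-anchor direction: a
#' stretched bond (`y_l > y_cr,eq`) pulls the element toward its wall
#' anchor, a compressed one pushes it away, and the force vanishes at the
#' equilibrium bond length.
#'
#' @param y_l bond length (lattice units).
#' @param sigma_lat spring constant (lattice units).
#' @param y_eq equilibrium bond length (lattice units).
#' @param direction unit vector from the element toward the anchor
#'   (default straight down toward the wall).
#' @return force vector (length 2).
#' @export
bond_force <- function(y_l, sigma_lat, y_eq, direction = c(0, -1)) {
  sigma_lat * (y_l - y_eq) * direction
}

#' Forward (bond formation) probability
#'
#' `P_f = 1 - exp(-k_f Nl dt)`, with `Nl` the fraction of surface elements
#' whose ligand is actually probing the wall (within the critical
#' distance).
#'
#' @param k_f forward rate (1/lattice time).
#' @param Nl probing-ligand fraction (or count, by convention of the
#'   caller).
#' @param dt time step (default 1).
#' @return probability in `[0, 1)`.
#' @export
forward_probability <- function(k_f, Nl, dt = 1) {
  if (any(k_f < 0) || any(Nl < 0)) stop("k_f and Nl must be non-negative")
  1 - exp(-k_f * Nl * dt)
}

#' Reverse (bond rupture) probability
#'
#' `P_r = 1 - exp(-k_r0 exp[(sigma - sigma*)(y_l - y_cr,eq)^2/(2 kBT)] dt)`.
#' With slip bonds (`sigma > sigma*`) rupture accelerates with bond
#' strain; at `sigma = sigma*` the strain dependence vanishes (catch/slip
#' crossover).  The inner exponent is clamped (with a warning) where it
#' would overflow, giving `P_r = 1`.
#'
#' @param y_l bond length (lattice units).
#' @param k_r0 unstressed reverse rate (1/lattice time).
#' @param sigma_lat,sigma_eq_lat spring and equilibrium spring constants.
#' @param y_eq equilibrium bond length.
#' @param kBT thermal potential (lattice units).
#' @param dt time step (default 1).
#' @return probability in `[0, 1]`.
#' @export
reverse_probability <- function(y_l, k_r0, sigma_lat, sigma_eq_lat, y_eq,
                                kBT, dt = 1) {
  ex <- (sigma_lat - sigma_eq_lat) * (y_l - y_eq)^2 / (2 * kBT)
  if (any(ex > 500)) {
    warning("rupture exponent overflow: probability clamped to 1")
    ex <- pmin(ex, 500)
  }
  1 - exp(-k_r0 * exp(ex) * dt)
}

#' Van der Waals-like wall repulsion
#'
#' `F_w = H_k/(8 sqrt(2)) sqrt(r / eps^5)` applied along the wall's
#' positive normal at the particle centroid — a pure repulsion preventing
#' wall contact.  Separations below `eps_floor` are evaluated at the floor
#' (declared regularization).
#'
#' @param eps particle-wall separation distance (lattice units, > 0).
#' @param r particle (equivalent) radius.
#' @param Hk Hamaker constant (lattice units).
#' @param eps_floor regularization floor for the separation.
#' @return force vector `c(0, F)` pointing away from the wall.
#' @export
vdw_wall_force <- function(eps, r, Hk, eps_floor = 0.05) {
  if (eps <= 0) stop("separation distance must be positive")
  eps <- max(eps, eps_floor)
  c(0, Hk / (8 * sqrt(2)) * sqrt(r / eps^5))
}

#' One stochastic bond-update sweep
#'
#' Formation first: every ligand-bearing, bond-free element whose gap to
#' the wall is below the critical distance forms a bond with probability
#' `P_f` (anchor fixed at the wall foot point).  Then rupture: every
#' pre-existing bond breaks with its strain-dependent probability `P_r`.
#' A bond formed in this sweep cannot rupture in the same sweep.
#'
#' @param bonds list with logical `ligand`, logical `active` and numeric
#'   `anchor_x` per element (as returned by this function or freshly
#'   initialized with `active = FALSE`).
#' @param elements `n x 2` matrix of element centroid positions; the wall
#'   is the line y = 0.
#' @param params an [adhesion_params()] object.
#' @param dt time step (default 1).
#' @return updated bonds list; attribute `"events"` holds a data frame of
#'   the formation/rupture events of this sweep (element, event, y_l).
#' @export
update_bonds <- function(bonds, elements, params, dt = 1) {
  gap <- elements[, 2]
  candidates <- bonds$ligand & !bonds$active & gap < params$y_cr
  n_probing <- sum(bonds$ligand & gap < params$y_cr)
  Pf <- forward_probability(params$kf_dt, n_probing / nrow(elements), dt)
  formed <- candidates & runif(length(gap)) < Pf
  bonds$active[formed] <- TRUE
  bonds$anchor_x[formed] <- elements[formed, 1]
  pre <- bonds$active & !formed
  y_l <- sqrt((bonds$anchor_x - elements[, 1])^2 + gap^2)
  broke <- rep(FALSE, length(gap))
  if (any(pre)) {
    Pr <- reverse_probability(
      y_l[pre], params$kr0_dt, params$sigma_lat, params$sigma_eq_lat,
      params$y_eq, params$kBT, dt
    )
    broke[pre] <- runif(sum(pre)) < Pr
    bonds$active[broke] <- FALSE
  }
  ev <- rbind(
    if (any(formed)) {
      data.frame(
        element = which(formed), event = "form", y_l = y_l[formed]
      )
    },
    if (any(broke)) {
      data.frame(
        element = which(broke), event = "break", y_l = y_l[broke]
      )
    }
  )
  attr(bonds, "events") <- ev
  bonds
}

#' Total adhesive force and moment
#'
#' Integrates the per-element bond forces over the particle perimeter
#' (element forces weighted by element length) and accumulates their
#' moment about the particle centroid.
#'
#' @param bonds bonds list (see [update_bonds()]).
#' @param elements `n x 2` element centroid positions.
#' @param lengths element lengths.
#' @param params an [adhesion_params()] object.
#' @param x_c particle centroid.
#' @return list with `force` (length 2) and scalar `moment`.
#' @export
total_adhesive_force <- function(bonds, elements, lengths, params, x_c) {
  Fx <- Fy <- M <- 0
  for (k in which(bonds$active)) {
    dxa <- bonds$anchor_x[k] - elements[k, 1]
    dya <- -elements[k, 2]
    y_l <- sqrt(dxa^2 + dya^2)
    f <- bond_force(
      y_l, params$sigma_lat, params$y_eq, c(dxa, dya) / y_l
    ) * lengths[k]
    Fx <- Fx + f[1]
    Fy <- Fy + f[2]
    r <- elements[k, ] - x_c
    M <- M + r[1] * f[2] - r[2] * f[1]
  }
  list(force = c(Fx, Fy), moment = M)
}
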