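#' Run a near-wall particle adhesion simulation
#'
#' Couples the lattice Boltzmann fluid, the MLS immersed boundary, the
#' stochastic bond kinetics and the rigid-body dynamics in one time loop:
#' per step, flow update with the direct-forcing body force, probe-based
#' load evaluation, bond formation/rupture sweep, explicit second-order
#' rigid-body update, boundary motion.  The channel is x-periodic with a
#' fixed bottom wall (the vessel wall) and a moving top wall imposing the
#' linear shear; the fluid starts from the developed Couette base state
#' and the particle from rest.  `Re = H u_max / nu` sets the top-wall
#' velocity from the configured relaxation time.
#'
#' @param config an [simulation_config()] object (or a list of fields
#'   passed to it).
#' @return an object of class `lbad_sim`: the trajectory record (a tibble
#'   with normalized time `t_conv = t u_max/H`, centroid position, angle,
#'   `ux_umax`, `omega_norm = Omega H/u_max`, minimum separation
#'   `y_min_H`, bond counts), window metrics, final fluid fields and
#'   marker/bond state, plus the run manifest.
#' @export
run_near_wall_simulation <- function(config) {
  if (!inherits(config, "lbad_config")) config <- simulation_config(config)
  H <- config$H_nodes - 1
  Ny <- config$H_nodes
  Nx <- as.integer(round(config$domain_H * H))
  nu <- lbm_viscosity(config$tau)
  u_max <- config$Re * nu / H
  if (u_max > 0.05)
    warning("u_max = ", signif(u_max, 3),
            " lattice units exceeds 0.05; increase H_nodes or lower tau")
  particle <- make_particle(
    shape = config$shape, aspect_ratio = config$aspect_ratio, H = H,
    d_over_H = config$d_over_H, y0_H = config$y0_H, theta0 = config$theta0,
    x_c0 = Nx / 2, y_c0_H = config$y_c0_H
  )
  params <- adhesion_params(
    H = H, nu = nu, sigma = config$sigma, kf_kr0 = config$kf_kr0,
    kr0_dt = config$kr0_dt, kBT_lat = config$kBT_lat,
    Hk_lat = config$Hk_lat, hk_scale = config$hk_scale,
    y_cr_H = config$y_cr_H, H_nodes = config$H_nodes,
    r_eq_lat = sqrt(particle$area / pi)
  )
  set.seed(config$seed)
  ligand <- seed_ligands(particle$boundary$n, config$rho_l)
  dump_prefix <- file.path(config$dump_dir, "fields")
  if (config$dump_every > 0 && !dir.exists(config$dump_dir)) {
    dir.create(config$dump_dir, recursive = TRUE)
  }
  t0 <- Sys.time()
  res <- cpp_run_near_wall(list(
    Nx = Nx, Ny = Ny, tau = config$tau, u_max = u_max,
    nsteps = as.integer(config$nsteps),
    sample_every = as.integer(config$sample_every),
    markers = particle$boundary$markers, ligand = ligand,
    x_c0 = particle$x_c[1], y_c0 = particle$x_c[2],
    theta0 = particle$theta, mass = particle$mass,
    inertia = particle$inertia,
    sigma_lat = params$sigma_lat, y_cr_lat = params$y_cr,
    y_eq_lat = params$y_eq, kf_dt = params$kf_dt, kr0_dt = params$kr0_dt,
    kBT_lat = params$kBT, Hk_lat = params$Hk, r_eq_lat = params$r_eq,
    eps_floor = config$eps_floor, probe_len = config$probe_len,
    mls_rs = config$mls_rs, dump_every = as.integer(config$dump_every),
    dump_prefix = dump_prefix
  ))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  tr <- res$trajectory
  n_lig <- max(res$n_ligands, 1L)
  traj <- tibble::tibble(
    step = tr[, 1],
    t_conv = tr[, 1] * u_max / H,
    x_c_H = (particle$x_c[1] + tr[, 2]) / H,
    y_c_H = tr[, 3] / H,
    theta = tr[, 4],
    ux_umax = tr[, 5] / u_max,
    uy_umax = tr[, 6] / u_max,
    omega_norm = tr[, 7] * H / u_max,
    y_min_H = tr[, 8] / H,
    n_active = as.integer(tr[, 9]),
    n_max = as.integer(tr[, 10]),
    n_total = res$n_elements,
    n_ligands = res$n_ligands,
    force_x = tr[, 11],
    force_y = tr[, 12],
    moment = tr[, 13]
  )
  sim <- structure(list(
    trajectory = traj,
    config = config,
    params = params,
    particle = particle,
    u_max = u_max,
    nu = nu,
    H = H, Nx = Nx, Ny = Ny,
    fields = list(rho = res$rho, ux = res$ux, uy = res$uy),
    markers = res$markers,
    bond_active = res$bond_active,
    ligand = ligand,
    manifest = run_manifest(config),
    elapsed = elapsed
  ), class = "lbad_sim")
  sim$metrics <- trajectory_metrics(traj, config$window)
  sim
}

#' @export
print.lbad_sim <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<lbad_sim> %s AR%d | Re = %g, rho_l = %g, sigma = %g | H = %d nodes\n",
    x$config$shape, x$config$aspect_ratio, x$config$Re, x$config$rho_l,
    x$config$sigma, x$config$H_nodes
  ))
  cat(sprintf(
    "  %d steps (%.1f s) | y_min/H = %.4g, u_roll/u_max = %.4g, OmegaH/u_max = %.4g\n",
    x$config$nsteps, x$elapsed, m$y_min_H, m$u_roll, m$omega_norm
  ))
  cat(sprintf(
    "  active fraction = %.4g, P_a = %.4g | regimen: %s\n",
    m$active_fraction, m$P_a, classify_regimen(x)
  ))
  invisible(x)
}

#' Classify the particle-wall interaction regimen
#'
#' Rule-ordered classification of a trajectory's trailing window:
#' \enumerate{
#'   \item \emph{firm adhesion} — rolling and rotational velocities below
#'     the zero threshold with persistent bonds;
#'   \item \emph{sliding, not adhering} — persistent bonds, negligible
#'     rotation, finite longitudinal velocity;
#'   \item \emph{not adhering} — no persistent bonds and a steady
#'     separation above the critical bond distance (the particle has left
#'     the interaction range; it may still rotate freely with the shear);
#'   \item \emph{rolling, not adhering} — otherwise, when the rotational
#'     velocity is above threshold (transient bonds keep the particle
#'     near the wall while it rotates);
#' }
#' with \emph{not adhering} as the fallback.
#'
#' @param sim an `lbad_sim` (or a trajectory tibble).
#' @param vel_threshold zero-velocity threshold for `|u_roll/u_max|` and
#'   the shear-aligned rotational velocity `Omega H/u_max`.
#' @param persist_hi window fraction of bond-carrying samples above which
#'   bonds count as persistent.
#' @param persist_lo fraction below which bonds count as absent.
#' @param window trailing averaging window (fraction of the record).
#' @param y_cr_H critical bond distance over H.
#' @return one of `"firm_adhesion"`, `"sliding_not_adhering"`,
#'   `"rolling_not_adhering"`, `"not_adhering"`.
#' @export
classify_regimen <- function(sim, vel_threshold = NULL, persist_hi = NULL,
                             persist_lo = NULL, window = NULL,
                             y_cr_H = NULL) {
  if (inherits(sim, "lbad_sim")) {
    cfg <- sim$config
    traj <- sim$trajectory
    if (is.null(vel_threshold)) vel_threshold <- cfg$vel_threshold
    if (is.null(persist_hi)) persist_hi <- cfg$persist_hi
    if (is.null(persist_lo)) persist_lo <- cfg$persist_lo
    if (is.null(window)) window <- cfg$window
    if (is.null(y_cr_H)) y_cr_H <- cfg$y_cr_H
  } else {
    traj <- sim
    if (is.null(vel_threshold)) vel_threshold <- 5e-3
    if (is.null(persist_hi)) persist_hi <- 0.5
    if (is.null(persist_lo)) persist_lo <- 0.1
    if (is.null(window)) window <- 0.25
    if (is.null(y_cr_H)) y_cr_H <- 6.8e-3
  }
  n <- nrow(traj)
  m <- ceiling(window * n)
  if (m < 5)
    stop("no steady window: trajectory record too short to classify; run longer")
  w <- traj[seq(n - m + 1L, n), ]
  u <- abs(mean(w$ux_umax))
  # rolling means co-rotating with the shear (clockwise, negative Omega
  # with the moving wall on top); counter-rotating creep from bond
  # turnover is tether mechanics, not rolling, and counts as zero
  om <- max(0, -mean(w$omega_norm))
  bond_frac <- mean(w$n_active > 0)
  if (u < vel_threshold && om < vel_threshold && bond_frac >= persist_hi) {
    "firm_adhesion"
  } else if (bond_frac >= persist_hi && om < vel_threshold &&
             u >= vel_threshold) {
    "sliding_not_adhering"
  } else if (bond_frac <= persist_lo && mean(w$y_min_H) > y_cr_H) {
    "not_adhering"
  } else if (om >= vel_threshold) {
    "rolling_not_adhering"
  } else {
    "not_adhering"
  }
}

#' Probability of adhesion
#'
#' Time average of the ratio between the number of active bonds and the
#' maximum number of bonds that could be closed at that instant (the
#' ligand-bearing elements within the critical distance, given the
#' current geometry and orientation).  Samples with no closable bond
#' contribute zero; if no bond could ever close, `P_a = 0` by convention.
#'
#' @param sim an `lbad_sim` or trajectory tibble.
#' @param window trailing averaging window.
#' @return adhesion probability in `[0, 1]`.
#' @export
adhesion_probability <- function(sim, window = 0.25) {
  if (inherits(sim, "lbad_sim")) {
    window <- sim$config$window
    sim <- sim$trajectory
  }
  trajectory_metrics(sim, window)$P_a
}

#' Sweep a phase map over flow and particle parameters
#'
#' One seeded run per grid cell over Reynolds number, ligand density,
#' shape and bond strength; each cell reports the rolling velocity, the
#' adhesion probability and the interaction regimen.  A failed cell is
#' flagged and the sweep continues.
#'
#' @param base_config the common configuration (an `lbad_config` or
#'   field list).
#' @param Re,rho_l,shapes,sigma vectors spanning the map.
#' @param verbose print one line per cell.
#' @return a tibble in long format: `Re`, `rho_l`, `shape`, `sigma`,
#'   `u_roll`, `omega_norm`, `y_min_H`, `P_a`, `active_fraction`,
#'   `label`, `failed`.
#' @export
sweep_phase_map <- function(base_config, Re = c(0.01, 0.1, 1),
                            rho_l = c(0.3, 0.5, 0.7, 0.9),
                            shapes = "circle", sigma = 2,
                            verbose = FALSE) {
  if (!inherits(base_config, "lbad_config"))
    base_config <- simulation_config(base_config)
  grid <- expand.grid(
    Re = Re, rho_l = rho_l, shape = shapes, sigma = sigma,
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- unclass(base_config)
    cfg$Re <- grid$Re[i]
    cfg$rho_l <- grid$rho_l[i]
    cfg$shape <- grid$shape[i]
    cfg$sigma <- grid$sigma[i]
    if (cfg$shape == "ellipse" && cfg$aspect_ratio == 1) cfg$aspect_ratio <- 2
    cfg$seed <- base_config$seed + i
    out <- tryCatch({
      sim <- run_near_wall_simulation(simulation_config(cfg))
      m <- sim$metrics
      tibble::tibble(
        Re = grid$Re[i], rho_l = grid$rho_l[i], shape = cfg$shape,
        sigma = grid$sigma[i], u_roll = m$u_roll,
        omega_norm = m$omega_norm, y_min_H = m$y_min_H, P_a = m$P_a,
        active_fraction = m$active_fraction,
        label = classify_regimen(sim), failed = FALSE
      )
    }, error = function(e) {
      warning("phase-map cell failed (Re = ", grid$Re[i], ", rho_l = ",
              grid$rho_l[i], "): ", conditionMessage(e))
      tibble::tibble(
        Re = grid$Re[i], rho_l = grid$rho_l[i], shape = cfg$shape,
        sigma = grid$sigma[i], u_roll = NA_real_, omega_norm = NA_real_,
        y_min_H = NA_real_, P_a = NA_real_, active_fraction = NA_real_,
        label = NA_character_, failed = TRUE
      )
    })
    if (verbose) {
      cat(sprintf(
        "Re = %-5g rho_l = %-4g sigma = %g %s -> %s\n", grid$Re[i],
        grid$rho_l[i], grid$sigma[i], cfg$shape,
        if (out$failed) "FAILED" else out$label
      ))
    }
    out
  })
  do.call(rbind, rows)
}

#' Microfluidic chip geometry
#'
#' Rectangular single-channel chip with the geometry of the cell-rolling
#' validation experiment: width `W = 210` um, height `H = 42` um, length
#' `L = 2.70` cm, rolling cells of diameter `d = 15` um.
#'
#' @param W channel width (um).
#' @param H channel height (um).
#' @param L channel length (cm).
#' @param Q flow rate(s) (nL/min).
#' @param d cell/particle diameter (um).
#' @return an object of class `lbad_chip`.
#' @export
chip_geometry <- function(W = 210, H = 42, L = 2.7,
                          Q = c(50, 100, 150, 200), d = 15) {
  if (any(c(W, H, L, d) <= 0) || any(Q < 0))
    stop("chip dimensions and flow rates must be positive")
  if (d >= H) stop("cell diameter d must be smaller than the channel height")
  structure(list(W = W, H = H, L = L, Q = Q, d = d), class = "lbad_chip")
}

#' Mean velocity and wall shear rate of the chip flow
#'
#' `U = Q/(W H)` and `S = 6 Q/(W H^2)` with the flow rate converted from
#' nL/min to um^3/s.
#'
#' @param chip an [chip_geometry()] object.
#' @return tibble with `Q` (nL/min), `U` (um/s) and `S` (1/s).
#' @export
chip_flow_quantities <- function(chip) {
  Q_um3s <- chip$Q * 1e6 / 60
  tibble::tibble(
    Q = chip$Q,
    U = Q_um3s / (chip$W * chip$H),
    S = 6 * Q_um3s / (chip$W * chip$H^2)
  )
}

#' Theoretical rolling velocity in a rectangular channel
#'
#' Closed form for a rigid sphere of diameter `d` rolling along the wall
#' of a rectangular channel under flow rate `Q`:
#' `u_th = (3/2) (Q/(W H)) [1 - (1 - d/H)^2]` (um/s).
#'
#' @param chip an [chip_geometry()] object.
#' @param d optional diameter override (um), e.g. for the d +/- 3 um
#'   envelope.
#' @return numeric vector of theoretical rolling velocities, one per flow
#'   rate.
#' @export
#' @examples
#' chip <- chip_geometry()
#' theoretical_rolling_velocity(chip)   # 83.16, 166.3, 249.5, 332.6 um/s
theoretical_rolling_velocity <- function(chip, d = NULL) {
  if (is.null(d)) d <- chip$d
  if (d >= chip$H)
    stop("cell diameter d must be smaller than the channel height")
  Q_um3s <- chip$Q * 1e6 / 60
  1.5 * Q_um3s / (chip$W * chip$H) * (1 - (1 - d / chip$H)^2)
}

#' Map a chip flow rate onto a simulation configuration
#'
#' The chip's wall shear rate `S = 6Q/(W H^2)` and height fix the lattice
#' Reynolds number via `u_max = S H` and `Re = S H^2 / nu_water`; the
#' simulated particle diameter matches the cell diameter (`d/H`).
#'
#' @param chip an [chip_geometry()] object.
#' @param Q flow rate (nL/min).
#' @param base_config configuration the chip-matched fields are merged
#'   into.
#' @param nu_water kinematic viscosity of water (um^2/s).
#' @return an `lbad_config` with matched `Re` and `d_over_H`.
#' @export
chip_matched_config <- function(chip, Q, base_config = simulation_config(),
                                nu_water = 1e6) {
  S <- 6 * (Q * 1e6 / 60) / (chip$W * chip$H^2)
  cfg <- unclass(base_config)
  cfg$Re <- S * chip$H^2 / nu_water
  cfg$d_over_H <- chip$d / chip$H
  cfg$shape <- "circle"
  cfg$aspect_ratio <- 1
  simulation_config(cfg)
}

#' Rolling-velocity validation against the closed-form line
#'
#' Runs one chip-matched simulation per flow rate (stock: Q = 50, 100,
#' 150, 200 nL/min at ligand density 0.3), converts the simulated rolling
#' velocity to physical units via `u_max = S H`, fits the least-squares
#' line of rolling velocity versus flow rate, and reports the goodness of
#' fit together with the theoretical envelope spanned by the cell
#' diameter spread `d +/- d_spread`.
#'
#' @param chip an [chip_geometry()] object (its `Q` vector sets the runs).
#' @param base_config common configuration for the runs (reduced
#'   resolutions are fine; `rho_l` should be 0.3 to match the validation
#'   condition).
#' @param d_spread half-width of the cell-diameter envelope (um).
#' @param nu_water kinematic viscosity of water (um^2/s).
#' @param verbose print one line per run.
#' @return list with the per-run `table` (Q, S, Re, u_roll_norm, u_sim,
#'   u_th and envelope), the `fit` (lm of u_sim ~ Q), `r_squared`,
#'   `slope`, `intercept`.
#' @export
rolling_velocity_validation <- function(chip, base_config,
                                        d_spread = 3, nu_water = 1e6,
                                        verbose = FALSE) {
  if (!inherits(base_config, "lbad_config"))
    base_config <- simulation_config(base_config)
  if (length(chip$Q) < 2)
    stop("need at least two flow rates for a linear fit")
  flow <- chip_flow_quantities(chip)
  u_th <- theoretical_rolling_velocity(chip)
  u_lo <- theoretical_rolling_velocity(chip, d = chip$d - d_spread)
  u_hi <- theoretical_rolling_velocity(chip, d = chip$d + d_spread)
  rows <- lapply(seq_along(chip$Q), function(i) {
    cfg <- chip_matched_config(chip, chip$Q[i], base_config, nu_water)
    cfg$seed <- base_config$seed + i
    sim <- run_near_wall_simulation(cfg)
    m <- sim$metrics
    if (verbose) {
      cat(sprintf("Q = %g nL/min: u_roll/u_max = %.4g (%s)\n", chip$Q[i],
                  m$u_roll, classify_regimen(sim)))
    }
    tibble::tibble(
      Q = chip$Q[i], S = flow$S[i], Re = cfg$Re, u_roll_norm = m$u_roll,
      u_sim = m$u_roll * flow$S[i] * chip$H,
      u_th = u_th[i], u_th_lo = u_lo[i], u_th_hi = u_hi[i],
      rolling = abs(m$u_roll) >= base_config$vel_threshold
    )
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$rolling)) {
    warning("non-rolling runs excluded from the fit: Q = ",
            paste(tab$Q[!tab$rolling], collapse = ", "))
  }
  use <- tab[tab$rolling, ]
  if (nrow(use) < 2) stop("fewer than two rolling runs: cannot fit a line")
  fit <- lm(u_sim ~ Q, data = use)
  list(
    table = tab,
    fit = fit,
    r_squared = summary(fit)$r.squared,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1])
  )
}
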