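test_that("chip hydraulics reproduce the closed-form velocities and shear rates", {
  chip <- chip_geometry(W = 210, H = 42, L = 2.7,
                        Q = c(50, 100, 150, 200), d = 15)
  flow <- chip_flow_quantities(chip)
  expect_equal(flow$U[1], 94.48, tolerance = 1e-3)
  expect_equal(flow$U, c(94.48, 188.9, 283.4, 377.9), tolerance = 1e-3)
  expect_equal(flow$S, c(13.5, 27, 40.5, 54), tolerance = 1e-3)
  u_th <- theoretical_rolling_velocity(chip)
  expect_equal(u_th[1], 83.15, tolerance = 1e-3)
  expect_equal(u_th[4], 333.0, tolerance = 2e-3)
  # d -> H limit: centerline factor (3/2) Q/(WH)
  big <- chip_geometry(Q = 50, d = 42 - 1e-9)
  expect_equal(theoretical_rolling_velocity(big), 1.5 * 94.48,
               tolerance = 1e-3)
  expect_error(theoretical_rolling_velocity(chip, d = 42), "smaller")
  expect_error(chip_geometry(d = 50), "smaller")
  z <- chip_flow_quantities(chip_geometry(Q = 0))
  expect_equal(z$U, 0)
  expect_equal(z$S, 0)
})

test_that("chip-matched configurations map shear rate to Reynolds number", {
  chip <- chip_geometry()
  cfg <- chip_matched_config(chip, 150, simulation_config(H_nodes = 33,
                                                          domain_H = 2))
  # Re = S H^2 / nu_water with S = 40.5 1/s, H = 42 um, nu = 1e6 um^2/s
  expect_equal(cfg$Re, 40.5 * 42^2 / 1e6, tolerance = 1e-3)
  expect_equal(cfg$d_over_H, 15 / 42)
  expect_error(
    rolling_velocity_validation(chip_geometry(Q = 50),
                                simulation_config()),
    "two flow rates"
  )
})

test_that("adhesion probability averages the closable-bond ratio", {
  traj <- tibble::tibble(
    y_min_H = 5e-3, ux_umax = 0, omega_norm = 0,
    n_active = c(0L, 1L, 2L, 1L), n_max = c(0L, 2L, 4L, 2L),
    n_total = 10L
  )
  # samples: 0 (by convention), 0.5, 0.5, 0.5
  expect_equal(adhesion_probability(traj, window = 1), 0.375)
  never <- tibble::tibble(
    y_min_H = 5e-2, ux_umax = 0, omega_norm = 0,
    n_active = rep(0L, 6), n_max = rep(0L, 6), n_total = 10L
  )
  expect_equal(adhesion_probability(never, window = 1), 0)
  full <- tibble::tibble(
    y_min_H = 5e-3, ux_umax = 0, omega_norm = 0,
    n_active = rep(3L, 6), n_max = rep(3L, 6), n_total = 10L
  )
  expect_equal(adhesion_probability(full, window = 1), 1)
})

test_that("regimen classification follows the documented rule order", {
  base <- function(u, om, act, ymin) {
    tibble::tibble(
      y_min_H = ymin, ux_umax = u, omega_norm = om,
      n_active = act, n_max = pmax(act, 1L), n_total = 20L
    )
  }
  n <- 40
  firm <- base(rep(1e-4, n), rep(1e-4, n), rep(2L, n), rep(6e-3, n))
  expect_equal(classify_regimen(firm), "firm_adhesion")
  slide <- base(rep(0.02, n), rep(1e-4, n), rep(2L, n), rep(6.5e-3, n))
  expect_equal(classify_regimen(slide), "sliding_not_adhering")
  # detached: no bonds, gap above y_cr, still rotating with the shear
  away <- base(rep(0.05, n), rep(-0.3, n), rep(0L, n), rep(8e-3, n))
  expect_equal(classify_regimen(away), "not_adhering")
  # transient bonds + rotation -> rolling
  roll <- base(rep(0.05, n), rep(-0.3, n),
               rep(c(1L, 0L), n / 2), rep(6.6e-3, n))
  expect_equal(classify_regimen(roll), "rolling_not_adhering")
  expect_error(classify_regimen(firm[1:3, ]), "steady window")
})

test_that("a 1x1 sweep wraps a single run and reports its metrics", {
  cfg <- simulation_config(
    H_nodes = 33, domain_H = 2, tau = 1, Re = 0.1, rho_l = 0,
    Hk_lat = 0, y_c0_H = 0.5, d_over_H = 0.2,
    nsteps = 3000, sample_every = 100, seed = 5
  )
  map <- sweep_phase_map(cfg, Re = 0.1, rho_l = 0, shapes = "circle",
                         sigma = 2)
  expect_equal(nrow(map), 1L)
  expect_false(map$failed)
  expect_true(map$label %in% c(
    "firm_adhesion", "sliding_not_adhering", "rolling_not_adhering",
    "not_adhering"
  ))
  expect_true(map$P_a >= 0 && map$P_a <= 1)
})
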