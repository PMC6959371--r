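test_that("ligand seeding is uniform, bounded and reproducible", {
  expect_true(all(seed_ligands(500, 1, seed = 3)))
  expect_false(any(seed_ligands(500, 0, seed = 3)))
  # binomial check at rho_l = 0.5 over 1e4 elements (3 sigma)
  lig <- seed_ligands(1e4, 0.5, seed = 99)
  expect_lt(abs(mean(lig) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_identical(seed_ligands(100, 0.4, seed = 7),
                   seed_ligands(100, 0.4, seed = 7))
  expect_error(seed_ligands(10, 1.5), "rho_l")
})

test_that("bond force is linear in stretch with the correct sign", {
  y_eq <- 3.4e-3
  # null force at the equilibrium bond length
  expect_equal(bond_force(y_eq, 2, y_eq), c(0, 0))
  # sigma = 2, stretched to y_cr: magnitude 2 * 3.4e-3 (H-normalized units)
  f <- bond_force(6.8e-3, 2, y_eq)
  expect_equal(f, 2 * 3.4e-3 * c(0, -1))
  # compressed bond pushes away from the anchor
  fc <- bond_force(2e-3, 2, y_eq)
  expect_gt(fc[2], 0)
})

test_that("forward probability matches its analytic limits", {
  expect_equal(forward_probability(0, 1), 0)
  expect_equal(forward_probability(1, 0), 0)
  expect_equal(forward_probability(log(2), 1), 0.5)
  p <- forward_probability(1, c(0.1, 1, 10, 100))
  expect_true(all(diff(p) > 0))
  expect_lt(1 - p[4], 1e-10)
  expect_error(forward_probability(-1, 1), "non-negative")
})

test_that("reverse probability follows the slip-bond kinetics", {
  k_r0 <- 1e-3; y_eq <- 0.2; kBT <- 0.01
  # zero stretch: P_r = 1 - exp(-k_r0 dt)
  expect_equal(reverse_probability(y_eq, k_r0, 2, 1, y_eq, kBT),
               1 - exp(-k_r0))
  # sigma = sigma*: strain independence (catch/slip crossover)
  p1 <- reverse_probability(0.5, k_r0, 1, 1, y_eq, kBT)
  p2 <- reverse_probability(5.0, k_r0, 1, 1, y_eq, kBT)
  expect_equal(p1, p2)
  # doubling the stretch quadruples the inner exponent
  s <- 0.05
  pa <- reverse_probability(y_eq + s, k_r0, 2, 1, y_eq, kBT)
  pb <- reverse_probability(y_eq + 2 * s, k_r0, 2, 1, y_eq, kBT)
  ex_a <- log(-log(1 - pa) / k_r0)
  ex_b <- log(-log(1 - pb) / k_r0)
  expect_equal(ex_b, 4 * ex_a, tolerance = 1e-10)
  # slip-bond monotonicity in stretch
  ps <- reverse_probability(y_eq + seq(0, 1, 0.1), k_r0, 2, 1, y_eq, kBT)
  expect_true(all(diff(ps) >= 0))
  expect_warning(
    pover <- reverse_probability(100, k_r0, 2, 1, y_eq, 1e-8),
    "clamped"
  )
  expect_equal(pover, 1)
})

test_that("bond sweeps respect the gap gate and the tie-break rule", {
  params <- adhesion_params(H = 100, nu = 1 / 6)
  n <- 50
  bonds <- list(ligand = rep(TRUE, n), active = rep(FALSE, n),
                anchor_x = rep(0, n))
  far <- cbind(seq_len(n), rep(10 * params$y_cr, n))
  set.seed(1)
  b2 <- update_bonds(bonds, far, params)
  expect_false(any(b2$active))
  # forced formation: huge forward rate, zero reverse rate
  p_on <- params; p_on$kf_dt <- 1e9; p_on$kr0_dt <- 0
  near <- cbind(seq_len(n), rep(0.5 * params$y_cr, n))
  b3 <- update_bonds(bonds, near, p_on)
  expect_true(all(b3$active))
  expect_equal(b3$anchor_x, near[, 1])
  # a bond formed in a sweep cannot rupture in the same sweep
  p_onoff <- params; p_onoff$kf_dt <- 1e9; p_onoff$kr0_dt <- 1e9
  b4 <- update_bonds(bonds, near, p_onoff)
  expect_true(all(b4$active))
  # ... but pre-existing bonds do rupture
  b5 <- update_bonds(b4, near, p_onoff)
  expect_false(any(b5$active))
})

test_that("stationary-gap occupancy matches the birth-death equilibrium", {
  # fixed geometry: all elements within reach at constant bond length
  n <- 1e4
  params <- adhesion_params(H = 100, nu = 1 / 6, kr0_dt = 0.02)
  params$kf_dt <- 0.05 # per-step formation with Nl = 1
  gap <- params$y_eq # unstrained bonds
  elements <- cbind(seq_len(n), rep(gap, n))
  bonds <- list(ligand = rep(TRUE, n), active = rep(FALSE, n),
                anchor_x = elements[, 1])
  Pf <- forward_probability(params$kf_dt, 1)
  Pr <- reverse_probability(gap, params$kr0_dt, params$sigma_lat,
                            params$sigma_eq_lat, params$y_eq, params$kBT)
  set.seed(21)
  for (s in 1:600) bonds <- update_bonds(bonds, elements, params)
  occ <- mean(bonds$active)
  eq <- Pf / (Pf + Pr)
  expect_lt(abs(occ - eq), 3 * sqrt(eq * (1 - eq) / n))
})

test_that("wall repulsion follows the power law in gap and radius", {
  expect_equal(vdw_wall_force(0.1, 5, 0), c(0, 0))
  f1 <- vdw_wall_force(0.2, 5, 1e-3)[2]
  f2 <- vdw_wall_force(0.4, 5, 1e-3)[2]
  expect_equal(f2 / f1, 2^(-2.5), tolerance = 1e-12)
  f4 <- vdw_wall_force(0.2, 20, 1e-3)[2]
  expect_equal(f4 / f1, 2, tolerance = 1e-12)
  expect_gt(f1, 0) # repulsive, away from the wall
  expect_error(vdw_wall_force(0, 5, 1e-3), "positive")
  # regularized at the declared floor
  expect_equal(vdw_wall_force(1e-9, 5, 1e-3, eps_floor = 0.05),
               vdw_wall_force(0.05, 5, 1e-3))
})

test_that("total adhesive force equals the element-by-element oracle", {
  params <- adhesion_params(H = 100, nu = 1 / 6)
  b <- build_boundary(c(18, 18))
  pl <- place_boundary(b, c(50, 9.3))
  set.seed(4)
  bonds <- list(
    ligand = rep(TRUE, b$n),
    active = runif(b$n) < 0.3,
    anchor_x = pl$centroids[, 1] + runif(b$n, -0.5, 0.5)
  )
  none <- list(ligand = bonds$ligand, active = rep(FALSE, b$n),
               anchor_x = bonds$anchor_x)
  z <- total_adhesive_force(none, pl$centroids, pl$lengths, params,
                            c(50, 9.3))
  expect_equal(z$force, c(0, 0))
  expect_equal(z$moment, 0)
  # independent vectorized summation
  act <- which(bonds$active)
  dxa <- bonds$anchor_x[act] - pl$centroids[act, 1]
  dya <- -pl$centroids[act, 2]
  yl <- sqrt(dxa^2 + dya^2)
  mag <- params$sigma_lat * (yl - params$y_eq) * pl$lengths[act]
  fx <- mag * dxa / yl
  fy <- mag * dya / yl
  rx <- pl$centroids[act, 1] - 50
  ry <- pl$centroids[act, 2] - 9.3
  got <- total_adhesive_force(bonds, pl$centroids, pl$lengths, params,
                              c(50, 9.3))
  expect_equal(got$force, c(sum(fx), sum(fy)), tolerance = 1e-12)
  expect_equal(got$moment, sum(rx * fy - ry * fx), tolerance = 1e-12)
  # single stretched bond at the lowest element: net downward pull with a
  # moment consistent with its lever arm
  ph <- place_boundary(b, c(50, 9.8)) # lowest gap 0.8 > y_eq: stretched
  low <- which.min(ph$centroids[, 2])
  one <- list(ligand = rep(TRUE, b$n), active = seq_len(b$n) == low,
              anchor_x = ph$centroids[, 1] + 0.3)
  g1 <- total_adhesive_force(one, ph$centroids, ph$lengths, params,
                             c(50, 9.8))
  expect_lt(g1$force[2], 0)
  r1 <- ph$centroids[low, ] - c(50, 9.8)
  f1 <- g1$force
  expect_equal(g1$moment, r1[1] * f1[2] - r1[2] * f1[1], tolerance = 1e-12)
})
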