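test_that("velocity set satisfies the quadrature moment identities", {
  vs <- lbm_velocity_set()
  expect_equal(sum(vs$w), 1)
  expect_equal(colSums(vs$w * vs$e), c(0, 0))
  # second moment = cs2 * identity
  m2 <- t(vs$e) %*% (vs$w * vs$e)
  expect_equal(m2, diag(2) / 3, tolerance = 1e-15)
  expect_equal(vs$w[1], 4 / 9)
  expect_equal(vs$cs, 1 / sqrt(3))
})

test_that("equilibrium populations reproduce the closed form and its moments", {
  vs <- lbm_velocity_set()
  # rest state: f_eq = w_i
  expect_equal(as.vector(equilibrium_populations(1, c(0, 0))), vs$w)
  # term-by-term high-precision evaluation at u = (0.1, 0); this velocity
  # sits above the Mach guard, which must announce itself
  expect_warning(f <- equilibrium_populations(1, c(0.1, 0)), "Mach")
  expect_equal(f[1, 2], (1 / 9) * (1 + 0.3 + 0.045 - 0.015))
  for (i in 1:9) expect_equal(f[1, i], oracle_feq(i, 1, c(0.1, 0)))
  # moment identities at arbitrary states
  set.seed(11)
  rho <- runif(20, 0.5, 2)
  u <- matrix(runif(40, -0.03, 0.03), 20, 2)
  feq <- equilibrium_populations(rho, u)
  expect_equal(rowSums(feq), rho, tolerance = 1e-14)
  expect_equal(feq %*% ORACLE_E, u * rho, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_error(equilibrium_populations(-1, c(0, 0)), "density")
})

test_that("Guo forcing has zero mass moment and the damped momentum moment", {
  tau <- 0.8
  expect_equal(
    as.vector(guo_forcing_term(c(0.02, 0.01), c(0, 0), tau)), rep(0, 9)
  )
  set.seed(3)
  for (k in 1:5) {
    u <- runif(2, -0.05, 0.05)
    g <- runif(2, -1e-3, 1e-3)
    Fi <- guo_forcing_term(u, g, tau)
    expect_lt(abs(sum(Fi)), 1e-15)
    # brute-force summation over the nine velocities
    expect_equal(as.vector(Fi %*% ORACLE_E), (1 - 1 / (2 * tau)) * g,
                 tolerance = 1e-12)
  }
})

test_that("a uniform equilibrium state is a fixed point of collide-and-stream", {
  f <- lbm_init_populations(
    matrix(1, 8, 8), matrix(0.02, 8, 8), matrix(0.01, 8, 8)
  )
  f2 <- collide_and_stream(f, tau = 0.9, walls = FALSE)
  expect_equal(f2, f, tolerance = 1e-14)
})

test_that("fully periodic unforced runs conserve mass to round-off", {
  set.seed(5)
  f <- array(runif(16 * 12 * 9, 0.01, 0.1), dim = c(16, 12, 9))
  m0 <- sum(f)
  for (s in 1:100) f <- collide_and_stream(f, 0.8, walls = FALSE)
  expect_lt(abs(sum(f) - m0) / m0, 1e-13)
})

test_that("shear-wave perturbations decay at the analytic viscous rate", {
  Nx <- 32; Ny <- 32; tau <- 0.8
  nu <- lbm_viscosity(tau)
  k <- 2 * pi / Nx
  A <- 1e-4
  uy0 <- outer(1:Nx, 1:Ny, function(x, y) A * sin(k * (x - 1)))
  f <- lbm_init_populations(matrix(1, Nx, Ny), matrix(0, Nx, Ny), uy0)
  n <- 400
  for (s in 1:n) f <- collide_and_stream(f, tau, walls = FALSE)
  rate <- -log(max(abs(compute_moments(f)$uy)) / A) / n
  expect_equal(rate, nu * k^2, tolerance = 0.01)
})

test_that("moments apply the half-force momentum correction exactly", {
  Nx <- 6; Ny <- 6
  f <- lbm_init_populations(
    matrix(1, Nx, Ny), matrix(0.05, Nx, Ny), matrix(0, Nx, Ny)
  )
  m <- compute_moments(f)
  expect_equal(m$ux, matrix(0.05, Nx, Ny), tolerance = 1e-14)
  expect_equal(m$p, m$rho / 3)
  g <- list(gx = matrix(2e-3, Nx, Ny), gy = matrix(-1e-3, Nx, Ny))
  mf <- compute_moments(f, forcing = g)
  expect_equal(mf$ux - m$ux, 0.5 * g$gx / m$rho, tolerance = 1e-15)
  expect_equal(mf$uy - m$uy, 0.5 * g$gy / m$rho, tolerance = 1e-15)
  expect_error(compute_moments(array(0, dim = c(4, 4, 9))), "density")
})

test_that("Zou-He closure recovers the prescribed wall velocity exactly", {
  Nx <- 10; Ny <- 8
  f <- lbm_init_populations(
    matrix(1, Nx, Ny), matrix(0.01, Nx, Ny), matrix(0, Nx, Ny)
  )
  f <- collide_and_stream(f, 0.9, walls = TRUE)
  for (uw in c(0, 0.03)) {
    fb <- apply_wall_velocity_bc(f, "top", uw)
    fb <- apply_wall_velocity_bc(fb, "bottom", 0)
    m <- compute_moments(fb)
    expect_equal(m$ux[, Ny], rep(uw, Nx), tolerance = 1e-14)
    expect_equal(m$uy[, Ny], rep(0, Nx), tolerance = 1e-14)
    expect_equal(m$ux[, 1], rep(0, Nx), tolerance = 1e-14)
  }
})

test_that("plane Couette converges to the exact linear profile", {
  Ny <- 33; u_max <- 0.02
  st <- run_channel_flow(Nx = 4, Ny = Ny, tau = 1, nsteps = 30000,
                         u_top = u_max)
  ana <- u_max * (0:(Ny - 1)) / (Ny - 1)
  expect_lt(max(abs(st$ux[1, ] - ana)) / u_max, 1e-10)
})
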