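# Shared oracles and fixtures, independent of the package's C++ kernels.

# D2Q9 constants for brute-force checks
ORACLE_E <- cbind(
  c(0, 1, 0, -1, 0, 1, -1, -1, 1),
  c(0, 0, 1, 0, -1, 1, 1, -1, -1)
)
ORACLE_W <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))

# term-by-term evaluation of the equilibrium distribution
oracle_feq <- function(i, rho, u) {
  eu <- sum(ORACLE_E[i, ] * u)
  ORACLE_W[i] * rho * (1 + 3 * eu + 4.5 * eu^2 - 1.5 * sum(u^2))
}

# dense weighted-least-squares MLS oracle: fit a + b x + c y by explicitly
# solving the normal equations over all nodes inside the support
oracle_mls <- function(field, xp, yp, rs = 2.5) {
  Nx <- nrow(field)
  Ny <- ncol(field)
  g <- expand.grid(x = 0:(Nx - 1), y = 0:(Ny - 1))
  d <- sqrt((g$x - xp)^2 + (g$y - yp)^2)
  q <- d / rs
  w <- ifelse(q <= 0.5, 2 / 3 - 4 * q^2 + 4 * q^3,
    ifelse(q < 1, 4 / 3 * (1 - q)^3, 0)
  )
  keep <- w > 0
  P <- cbind(1, g$x[keep] - xp, g$y[keep] - yp)
  W <- diag(w[keep])
  u <- as.vector(field)[keep]
  a <- solve(t(P) %*% W %*% P, t(P) %*% W %*% u)
  as.vector(a) # value, d/dx, d/dy at the point
}

# Ramanujan approximation of the ellipse perimeter
oracle_ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
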