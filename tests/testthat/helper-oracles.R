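# Independent reference implementations used to cross-check the package's
# numerics. These deliberately use a different route (dense linear algebra,
# elementwise arithmetic in R) than the C++ code under test.

# Dense solve of the implicit diffusion system (I - r*L) x_new = x, with L
# the second-difference matrix under zero Dirichlet ghost points.
dense_diffuse_oracle <- function(x, kappa, grid, normalize = TRUE) {
  m <- length(x)
  r <- kappa / grid$delta^2
  A <- diag(1 + 2 * r, m)
  for (b in seq_len(m - 1)) {
    A[b, b + 1] <- -r
    A[b + 1, b] <- -r
  }
  out <- solve(A, x)
  if (normalize) out / sum(out) else out
}

# Brute-force Bayesian update: perceive then pointwise product, in plain R.
product_update_oracle <- function(x_i, x_j, alpha) {
  m <- length(x_i)
  perceived <- alpha * x_j + (1 - alpha) * rep(1 / m, m)
  post <- x_i * perceived
  post / sum(post)
}

oracle_moments <- function(x, grid) {
  mu <- sum(grid$points * x)
  c(mean = mu, variance = sum((grid$points - mu)^2 * x))
}

# A normalized random mass vector on the grid.
random_opinion <- function(grid, concentration = 1) {
  w <- stats::rgamma(length(grid$points), shape = concentration)
  w / sum(w)
}

# Tiny configs used across tests to keep runtimes low.
quick_config <- function(..., t_max = 50) {
  sim_config(t_max = t_max, ...)
}
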