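#' The discretized belief space
#'
#' Opinions live on the interval \[-1, 1\] of stances on a debated issue,
#' discretized to 200 equally spaced points \{-0.995, -0.985, ..., 0.995\}
#' with spacing 0.01. All opinion distributions share this grid.
#'
#' @return An object of class `belief_grid` with components
#'   \describe{
#'     \item{points}{the 200 belief values, strictly increasing and symmetric
#'       about 0}
#'     \item{delta}{the grid spacing, 0.01}
#'     \item{uniform}{the uniform reference distribution: equal mass 1/200
#'       per point}
#'   }
#' @export
#' @examples
#' g <- belief_grid()
#' range(g$points)
belief_grid <- function() {
  m <- 200L
  delta <- 0.01
  points <- seq(-0.995, 0.995, by = delta)
  stopifnot(length(points) == m)
  structure(
    list(points = points, delta = delta, uniform = rep(1 / m, m)),
    class = "belief_grid"
  )
}

#' @export
print.belief_grid <- function(x, ...) {
  cat(sprintf(
    "<belief_grid> %d points on [%g, %g], spacing %g\n",
    length(x$points), min(x$points), max(x$points), x$delta
  ))
  invisible(x)
}

check_opinion <- function(x, grid, arg = "x") {
  if (!is.numeric(x) || length(x) != length(grid$points)) {
    stop(sprintf(
      "`%s` must be a numeric vector with one mass per grid point (%d)",
      arg, length(grid$points)
    ), call. = FALSE)
  }
  if (any(x < 0)) stop(sprintf("`%s` has negative masses", arg), call. = FALSE)
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 0.99) {
    stop("`alpha` must be a single value in [0, 0.99]", call. = FALSE)
  }
  invisible(alpha)
}

#' Truncated-Gaussian opinion distribution
#'
#' Builds an agent's initial opinion: a Gaussian with mean `mu` and spread
#' `sigma` evaluated at the grid points and renormalized, i.e. truncated to
#' the belief space. Near the boundaries the realized mean is pulled inward
#' relative to `mu`.
#'
#' @param mu centre of the Gaussian, in \[-1, 1\].
#' @param sigma spread of the Gaussian; must be positive.
#' @param grid a [belief_grid()].
#' @return A normalized mass vector over the grid (sums to 1).
#' @export
#' @examples
#' g <- belief_grid()
#' x <- opinion_gaussian(0.9, 0.2, g)
#' opinion_moments(x, g)
opinion_gaussian <- function(mu, sigma, grid = belief_grid()) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || abs(mu) > 1) {
    stop("`mu` must be a single value in [-1, 1]", call. = FALSE)
  }
  w <- stats::dnorm(grid$points, mean = mu, sd = sigma)
  w / sum(w)
}

#' Mean and variance of an opinion distribution
#'
#' @param x a normalized mass vector over the grid.
#' @param grid a [belief_grid()].
#' @return Named numeric vector with components `mean` and `variance`.
#' @export
opinion_moments <- function(x, grid = belief_grid()) {
  check_opinion(x, grid)
  mu <- sum(grid$points * x)
  c(mean = mu, variance = sum((grid$points - mu)^2 * x))
}

#' Perception filter
#'
#' How a listener sees a messenger's opinion: a convex mixture
#' `alpha * x + (1 - alpha) * U` of the messenger's distribution with the
#' uniform reference U. `alpha` is the transparency of the filter: 0 is fully
#' opaque (the listener sees only uniform noise), values near 1 are fully
#' transparent. In-group bias means using a larger `alpha` for in-group
#' messengers than for out-group messengers.
#'
#' @param x the messenger's normalized opinion.
#' @param alpha filter transparency, in \[0, 0.99\].
#' @param grid a [belief_grid()].
#' @return The perceived (normalized) distribution.
#' @export
perceive <- function(x, alpha, grid = belief_grid()) {
  check_opinion(x, grid)
  check_alpha(alpha)
  cpp_perceive(x, alpha)
}

#' Bayesian social update
#'
#' The listener treats its own opinion as the prior and the perceived
#' messenger opinion as the likelihood: the posterior is the pointwise
#' product `x_i * (alpha * x_j + (1 - alpha) * U)`, renormalized. Only the
#' listener's opinion changes; the messenger is read, never written.
#'
#' @param x_i the listener's normalized opinion (prior).
#' @param x_j the messenger's normalized opinion.
#' @param alpha perception filter transparency, in \[0, 0.99\].
#' @param grid a [belief_grid()].
#' @return The listener's posterior opinion (normalized).
#' @export
social_update <- function(x_i, x_j, alpha, grid = belief_grid()) {
  check_opinion(x_i, grid, "x_i")
  check_opinion(x_j, grid, "x_j")
  check_alpha(alpha)
  cpp_social_update(x_i, x_j, alpha)
}

#' One implicit diffusion step (opinion decay during non-interaction)
#'
#' A non-interacting agent's opinion broadens by one backward-time
#' centred-space step of the heat equation `dx/dt = kappa * d2x/db2` with
#' zero Dirichlet values at ghost points one spacing outside the grid:
#' solve `(I - r L) x_new = x` with `r = kappa / delta^2` (one simulation
#' step per solve) via a tridiagonal (Thomas) solver. The Dirichlet sink
#' loses a little total mass at the boundaries each step, so the result is
#' renormalized by default to stay a probability distribution.
#'
#' @param x a normalized opinion mass vector.
#' @param kappa decay speed (belief units squared per step); non-negative.
#' @param grid a [belief_grid()].
#' @param normalize renormalize the solution to sum 1 (default `TRUE`).
#'   `FALSE` exposes the raw solve, e.g. to inspect boundary mass loss.
#' @return The diffused opinion.
#' @export
diffuse_step <- function(x, kappa, grid = belief_grid(), normalize = TRUE) {
  check_opinion(x, grid)
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) || kappa < 0) {
    stop("`kappa` must be a single non-negative number", call. = FALSE)
  }
  cpp_diffuse_step(x, kappa / grid$delta^2, normalize)
}
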