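test_that("the belief grid is the canonical 200-point discretization", {
  g <- belief_grid()
  expect_length(g$points, 200)
  expect_equal(g$points[1], -0.995)
  expect_equal(g$points[200], 0.995)
  expect_equal(unique(round(diff(g$points), 12)), 0.01)
  expect_equal(g$delta, 0.01)
  # symmetric about zero, strictly increasing
  expect_equal(g$points, -rev(g$points))
  expect_true(all(diff(g$points) > 0))
  # uniform reference: equal mass 1/200 per point, sums to one
  expect_equal(g$uniform, rep(0.005, 200))
  expect_equal(sum(g$uniform), 1)
})

test_that("truncated-Gaussian opinions are normalized with the expected shape", {
  g <- belief_grid()

  # symmetric case: mean exactly zero
  x <- opinion_gaussian(0, 0.2, g)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_equal(opinion_moments(x, g)[["mean"]], 0, tolerance = 1e-12)
  expect_equal(x, rev(x))

  # truncation near the boundary pulls the realized mean inward
  # (frozen from direct summation of the renormalized masses)
  x <- opinion_gaussian(0.9, 0.2, g)
  m <- opinion_moments(x, g)[["mean"]]
  expect_lt(m, 0.9)
  expect_equal(m, 0.7981626575, tolerance = 1e-9)

  # very wide Gaussian is nearly uniform: density ratio ~ exp(0.995^2/200)
  x <- opinion_gaussian(0, 10, g)
  expect_lt(max(x) / min(x), 1.01)

  expect_error(opinion_gaussian(0, -1, g), "sigma")
  expect_error(opinion_gaussian(0, 0, g), "sigma")
  expect_error(opinion_gaussian(2, 0.2, g), "mu")
})

test_that("opinion moments match closed forms", {
  g <- belief_grid()
  point <- replace(numeric(200), which(abs(g$points - 0.505) < 1e-9), 1)
  expect_equal(opinion_moments(point, g), c(mean = 0.505, variance = 0))
  expect_equal(opinion_moments(g$uniform, g)[["mean"]], 0, tolerance = 1e-12)
  two <- numeric(200)
  two[c(1, 200)] <- 0.5
  expect_equal(opinion_moments(two, g), c(mean = 0, variance = 0.995^2))
})

test_that("the perception filter mixes towards the uniform reference", {
  g <- belief_grid()
  set.seed(42)
  x <- random_opinion(g)

  # fully opaque filter: the listener sees pure uniform
  expect_equal(perceive(x, 0, g), g$uniform)
  # uniform messenger is a fixed point for any transparency
  expect_equal(perceive(g$uniform, 0.7, g), g$uniform)
  # point-mass messenger at transparency 0.5: mass 0.5 + 0.5/200 at the
  # point, 0.5/200 elsewhere
  point <- replace(numeric(200), 17, 1)
  out <- perceive(point, 0.5, g)
  expect_equal(out[17], 0.5025)
  expect_equal(out[-17], rep(0.0025, 199))
  expect_equal(sum(out), 1, tolerance = 1e-12)

  expect_error(perceive(x, 1, g), "alpha")
  expect_error(perceive(x, -0.1, g), "alpha")
})

test_that("the Bayesian social update matches the brute-force oracle", {
  g <- belief_grid()
  set.seed(7)
  for (alpha in c(0.1, 0.25, 0.5, 0.75, 0.99)) {
    x_i <- random_opinion(g)
    x_j <- random_opinion(g, concentration = 0.5)
    got <- social_update(x_i, x_j, alpha, g)
    expect_equal(got, product_update_oracle(x_i, x_j, alpha),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("social update identity cases leave the listener unchanged", {
  g <- belief_grid()
  set.seed(8)
  x_i <- random_opinion(g)
  # uniform messenger: multiplying by a constant then renormalizing
  expect_equal(social_update(x_i, g$uniform, 0.8, g), x_i, tolerance = 1e-12)
  # opaque filter: perceived distribution is uniform
  x_j <- random_opinion(g)
  expect_equal(social_update(x_i, x_j, 0, g), x_i, tolerance = 1e-12)
})

test_that("interacting sharpens: posterior variance drops for agreeing agents", {
  g <- belief_grid()
  x <- opinion_gaussian(0, 0.2, g)
  post <- social_update(x, x, 0.99, g)
  v_prior <- opinion_moments(x, g)[["variance"]]
  v_post <- opinion_moments(post, g)[["variance"]]
  expect_lt(v_post, v_prior)
  # for untruncated Gaussians the product halves the variance; the uniform
  # admixture at alpha = 0.99 shifts this only slightly (frozen from the
  # brute-force oracle)
  expect_equal(v_post, 0.02007136, tolerance = 1e-6)
  expect_equal(v_post / v_prior, 0.5, tolerance = 0.01)
})

test_that("influence strength is monotone in the filter transparency", {
  g <- belief_grid()
  set.seed(9)
  for (rep in 1:5) {
    x_i <- random_opinion(g)
    x_j <- random_opinion(g, concentration = 0.5)
    d <- vapply(
      seq(0, 0.99, by = 0.11),
      function(a) sum(abs(social_update(x_i, x_j, a, g) - x_i)),
      numeric(1)
    )
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("repeated mutual updating contracts variance towards certainty", {
  g <- belief_grid()
  x <- opinion_gaussian(0.3, 0.2, g)
  v <- opinion_moments(x, g)[["variance"]]
  for (it in 1:60) {
    x <- social_update(x, x, 0.99, g)
    v_new <- opinion_moments(x, g)[["variance"]]
    expect_lte(v_new, v + 1e-15)
    v <- v_new
  }
  expect_lt(v, 1e-4)  # essentially a single grid cell
})

test_that("implicit diffusion matches a dense linear solve", {
  g <- belief_grid()
  set.seed(10)
  for (kappa in c(2e-4, 5e-3)) {
    for (rep in 1:3) {
      x <- random_opinion(g)
      expect_equal(diffuse_step(x, kappa, g),
                   dense_diffuse_oracle(x, kappa, g), tolerance = 1e-10)
      expect_equal(diffuse_step(x, kappa, g, normalize = FALSE),
                   dense_diffuse_oracle(x, kappa, g, normalize = FALSE),
                   tolerance = 1e-10)
    }
  }
  # kappa = 0 is the exact identity
  x <- random_opinion(g)
  expect_identical(diffuse_step(x, 0, g), x)
  expect_error(diffuse_step(x, -1, g), "kappa")
})

test_that("diffusion broadens opinions and sinks mass at the boundaries", {
  g <- belief_grid()
  point <- replace(numeric(200), 100, 1)  # near the grid centre
  out <- diffuse_step(point, 2e-4, g)
  expect_gt(opinion_moments(out, g)[["variance"]],
            opinion_moments(point, g)[["variance"]])
  # one implicit step from a point mass spreads ~2*kappa of variance
  expect_equal(opinion_moments(out, g)[["variance"]], 2 * 2e-4,
               tolerance = 0.1)

  # Dirichlet ghost points: starting uniform, the raw solve loses mass at
  # the two boundary points while the interior is nearly unchanged
  raw <- diffuse_step(g$uniform, 2e-4, g, normalize = FALSE)
  expect_lt(raw[1], g$uniform[1])
  expect_lt(raw[200], g$uniform[200])
  expect_equal(raw[100], g$uniform[100], tolerance = 1e-6)
})

test_that("repeated diffusion converges to its long-run profile", {
  g <- belief_grid()
  x <- opinion_gaussian(0.5, 0.1, g)
  # long-run profile of the renormalized Dirichlet walk: iterate far ahead
  ref <- x
  for (it in 1:4000) ref <- diffuse_step(ref, 5e-3, g)
  v_old <- opinion_moments(x, g)[["variance"]]
  d_old <- max(abs(x - ref))
  growing <- TRUE
  for (it in 1:200) {
    x <- diffuse_step(x, 5e-3, g)
    d_new <- max(abs(x - ref))
    expect_lte(d_new, d_old + 1e-12)
    d_old <- d_new
    v_new <- opinion_moments(x, g)[["variance"]]
    if (growing) {
      # variance grows until boundary losses start to dominate
      growing <- v_new >= v_old - 1e-12
    }
    v_old <- v_new
  }
  expect_lt(d_old, 0.05 * max(ref))
})

test_that("every public opinion operation conserves normalization", {
  g <- belief_grid()
  set.seed(11)
  for (rep in 1:20) {
    x <- random_opinion(g, concentration = 0.3)
    y <- random_opinion(g)
    a <- runif(1, 0, 0.99)
    k <- runif(1, 0, 1e-3)
    for (out in list(
      perceive(x, a, g),
      social_update(x, y, a, g),
      diffuse_step(x, k, g),
      opinion_gaussian(runif(1, -1, 1), runif(1, 0.05, 1), g)
    )) {
      expect_equal(sum(out), 1, tolerance = 1e-12)
      expect_true(all(out >= 0))
    }
  }
})
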