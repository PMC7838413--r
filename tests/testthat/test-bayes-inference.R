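test_that("the speckle likelihood is the exponential density in the estimate", {
  expect_equal(likelihood(2, 2), 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(likelihood(0, 4), 0.25, tolerance = 1e-12)
  expect_error(likelihood(1, 0), "positive")
  expect_error(likelihood(-1, 1), "non-negative")
  # normalizes to 1 over the estimate, for several true coefficients
  for (mu in c(0.5, 2, 4)) {
    z <- stats::integrate(function(x) likelihood(x, mu), 0, Inf)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("the joint likelihood factorizes over independent estimates", {
  expect_equal(likelihood_multi(1.3, 2), likelihood(1.3, 2))
  expect_equal(likelihood_multi(c(1, 2, 3), 2), (1 / 8) * exp(-3),
               tolerance = 1e-12)
  expect_equal(likelihood_multi(c(1, 2, 3), 2), 6.2234e-3, tolerance = 1e-4)
  for (seed in 1:10) {
    mh <- withr::with_seed(seed, runif(5, 0, 6))
    mu <- withr::with_seed(seed + 100, runif(1, 0.2, 5))
    expect_equal(log(likelihood_multi(mh, mu)),
                 sum(log(likelihood(mh, mu))), tolerance = 1e-12)
  }
  expect_error(likelihood_multi(numeric(0), 2), "at least one")
})

test_that("the prior is the Gaussian with variance zeta * layer_mean", {
  pr <- suppressWarnings(prior_spec(0.4, 6.87e-2))
  # value at the mode
  expect_equal(prior_density(0.4, pr), 1 / sqrt(2 * pi * 0.4 * 6.87e-2),
               tolerance = 1e-12)
  expect_equal(prior_density(0.4, pr), 2.4066, tolerance = 1e-4)
  # symmetry about the layer mean
  d <- c(0.05, 0.2, 1)
  expect_equal(prior_density(0.4 + d, pr), prior_density(0.4 - d, pr))
  # full-line normalization; positive-axis truncation mass small for a
  # well-separated prior
  expect_equal(stats::integrate(function(x) prior_density(x, pr),
                                -Inf, Inf)$value, 1, tolerance = 1e-8)
  pr2 <- prior_spec(2, 1e-2)
  expect_equal(stats::integrate(function(x) prior_density(x, pr2),
                                0, Inf)$value, 1, tolerance = 1e-6)
  # the truncation-mass warning fires exactly when mass below zero > 1e-3
  expect_warning(prior_spec(0.4, 6.87e-2), "below zero")
  expect_silent(prior_spec(2, 1e-2))
  expect_error(prior_spec(-1, 0.1), "positive")
  expect_error(prior_spec(1, 0), "positive")
})

test_that("the posterior is normalized, non-negative and inside its grid", {
  for (seed in 1:10) {
    par <- withr::with_seed(seed, c(runif(1, 0.2, 5), runif(1, 1e-3, 1e-1)))
    pr <- suppressWarnings(prior_spec(par[1], par[2]))
    mh <- withr::with_seed(seed + 50, runif(3, 0, 3 * par[1]))
    po <- posterior(mh, pr)
    expect_true(all(po$density >= 0))
    expect_equal(trapz_check <- sum(diff(po$mu_grid) *
      (head(po$density, -1) + tail(po$density, -1)) / 2), 1,
      tolerance = 1e-6)
    m <- posterior_mean(po)
    expect_gt(m, min(po$mu_grid))
    expect_lt(m, max(po$mu_grid))
    expect_gte(posterior_variance(po), 0)
  }
  expect_warning(posterior(0, prior_spec(2, 1e-2)), "zero")
})

test_that("posterior mean is monotone in the observed estimate", {
  pr <- prior_spec(2, 5e-2)
  mh <- seq(0.01, 6, length.out = 25)
  means <- vapply(mh, function(x) posterior_mean(posterior(x, pr)), 0)
  expect_true(all(diff(means) > 0))
})

test_that("a vanishing prior width collapses the posterior onto the layer mean", {
  pr <- prior_spec(2, 1e-8)
  for (mh in c(0.1, 2, 5)) {
    po <- posterior(mh, pr)
    expect_equal(posterior_mean(po), 2, tolerance = 1e-3)
    expect_lt(posterior_variance(po), 1e-4)
  }
})

test_that("posterior mode is the refined argmax and scale invariant", {
  pr <- prior_spec(2, 1e-2)
  po <- posterior(2, pr)
  map1 <- posterior_map(po)
  # rescaling the tabulated density leaves the argmax unchanged
  po_scaled <- po
  po_scaled$density <- 5.7 * po$density
  expect_equal(posterior_map(po_scaled), map1, tolerance = 1e-12)
  # near-symmetric narrow posterior: mode close to mean, inside one grid step
  i <- which.max(po$density)
  expect_lt(abs(map1 - po$mu_grid[i]), diff(po$mu_grid[c(i - 1, i + 1)]))
  expect_lt(abs(map1 - posterior_mean(po)), 0.05)
})

test_that("quadrature matches the importance-sampling oracle", {
  pr <- suppressWarnings(prior_spec(0.4, 6.87e-2))
  po <- posterior(1.3, pr)
  or <- is_posterior_oracle(1.3, pr, n = 2e5, seed = 13)
  expect_lt(abs(posterior_mean(po) - or$mean), 3 * or$mean_se)
  expect_lt(abs(posterior_variance(po) - or$var), 3 * or$var_se)
})

test_that("the posterior concentrates on the truth as estimates accumulate", {
  mu_true <- 2
  pr <- prior_spec(1.5, 8e-2)  # deliberately misspecified layer mean
  bias <- sapply(c(1, 10, 100), function(k) {
    errs <- vapply(1:200, function(r) {
      mh <- withr::with_seed(r * 1000 + k, rexp(k, rate = 1 / mu_true))
      posterior_mean(posterior(mh, pr, n_grid = 1024)) - mu_true
    }, 0)
    mean(abs(errs))
  })
  expect_true(all(diff(bias) < 0))
})

test_that("voxelwise posterior-mean maps are equivariant and shrink error", {
  g <- tiny_geometry(n_depth = 60, axial_pitch = 0.0068)
  sim <- simulate_bscan(2, g, n_lines = 4, seed = 17)
  dr <- dr_estimate(sim$speckled)
  pr <- prior_spec(layer_mean(dr), 5e-2)
  em <- estimate_map(dr, pr, n_grid = 1024)
  # permuting A-lines permutes the output
  perm <- c(3, 1, 4, 2)
  dr_perm <- dr
  dr_perm$estimates <- dr$estimates[, perm]
  dr_perm$admissible_mask <- dr$admissible_mask[, perm]
  em_perm <- estimate_map(dr_perm, pr, n_grid = 1024)
  expect_equal(em_perm$values, em$values[, perm], tolerance = 1e-12)
  # masked voxels are NA, admissible ones finite
  expect_true(all(is.na(em$values[!dr$admissible_mask])))
  expect_true(all(is.finite(em$values[dr$admissible_mask])))
  # error reduction against the constant truth
  mask <- dr$admissible_mask
  rmse_dr <- sqrt(mean((dr$estimates[mask] - 2)^2))
  rmse_post <- sqrt(mean((em$values[mask] - 2)^2))
  expect_lt(rmse_post, rmse_dr)
})

test_that("estimate_map with concordant estimates and a tight prior is flat", {
  g <- tiny_geometry(n_depth = 10)
  est <- matrix(2, 10, 2)
  mask <- matrix(TRUE, 10, 2); mask[8:10, ] <- FALSE
  d <- structure(list(estimates = est, admissible_mask = mask,
                      truncation_fraction = 0.3, tail_mode = "none",
                      geometry = g), class = "oct_dr_map")
  # prior sd (0.014) must stay wider than the quadrature spacing near the
  # mode, so the tight-prior limit is still resolved by the grid
  em <- estimate_map(d, prior_spec(2, 1e-4), n_grid = 4096)
  expect_equal(em$values[mask], rep(2, sum(mask)), tolerance = 1e-3)
})
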