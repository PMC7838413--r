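#' Gaussian prior specification for the attenuation coefficient
#'
#' For a dilute suspension of identical scatterers the number of particles
#' in a voxel is Poisson, and for large counts approximately Gaussian; the
#' attenuation coefficient, proportional to that count, inherits a
#' Gaussian law with mean `layer_mean` and variance `zeta * layer_mean`,
#' where `zeta` is the scattering cross-section divided by the voxel
#' volume (mm^-1).  The density is used as printed, without renormalizing
#' for the positivity truncation; if the mass below zero exceeds 1e-3 a
#' warning is issued, since the un-renormalized density is then a poor
#' approximation on the positive axis.
#'
#' @param layer_mean Layer-mean attenuation coefficient (mm^-1, > 0).
#' @param zeta Prior width parameter (mm^-1, > 0); see
#'   [zeta_from_geometry()] to derive it from phantom physics.
#' @return An object of class `oct_prior`.
#' @export
prior_spec <- function(layer_mean, zeta) {
  if (!is.numeric(layer_mean) || length(layer_mean) != 1 || layer_mean <= 0)
    stop_input("`layer_mean` must be a single positive attenuation (mm^-1)")
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0)
    stop_input("`zeta` must be a single positive length^-1 (mm^-1)")
  mass_below_zero <- pnorm(0, layer_mean, sqrt(zeta * layer_mean))
  if (mass_below_zero > 1e-3)
    warning(sprintf(
      "prior places %.3g of its mass below zero; densities are used %s",
      mass_below_zero, "un-renormalized"), call. = FALSE)
  structure(list(layer_mean = layer_mean, zeta = zeta), class = "oct_prior")
}

#' @export
print.oct_prior <- function(x, ...) {
  cat(sprintf(
    "<oct_prior> mean %.4g mm^-1, zeta %.4g mm^-1 (variance %.4g mm^-2)\n",
    x$layer_mean, x$zeta, x$zeta * x$layer_mean))
  invisible(x)
}

log_likelihood <- function(mu_hat, mu_oct) {
  -log(mu_oct) - mu_hat / mu_oct
}

#' Speckle likelihood of a single DR estimate
#'
#' At leading order in the denominator fluctuations, a DR estimate made
#' from a speckled scan is exponentially distributed around the true
#' coefficient: `P(mu_hat | mu_oct) = (1 / mu_oct) exp(-mu_hat / mu_oct)`.
#' Evaluated in the log domain internally.  Vectorized over both
#' arguments.
#'
#' @param mu_hat Observed DR estimate(s) (mm^-1, >= 0).
#' @param mu_oct Candidate true coefficient(s) (mm^-1, > 0).
#' @return Density value(s), units mm.
#' @examples
#' likelihood(2, 2)  # 0.5 * exp(-1)
#' @export
likelihood <- function(mu_hat, mu_oct) {
  if (any(mu_oct <= 0)) stop_input("`mu_oct` must be positive")
  if (any(mu_hat < 0)) stop_input("`mu_hat` must be non-negative")
  exp(log_likelihood(mu_hat, mu_oct))
}

#' Joint speckle likelihood of k independent DR estimates
#'
#' For k independent co-registered estimates the joint likelihood is the
#' product of the single-estimate exponentials:
#' `(1 / mu_oct)^k exp(-sum(mu_hats) / mu_oct)`.
#'
#' @param mu_hats Vector of k >= 1 DR estimates (mm^-1, >= 0).
#' @param mu_oct Candidate true coefficient(s) (mm^-1, > 0); vectorized.
#' @return Density value(s), units mm^k.
#' @export
likelihood_multi <- function(mu_hats, mu_oct) {
  if (length(mu_hats) < 1) stop_input("`mu_hats` must contain at least one estimate")
  if (any(mu_oct <= 0)) stop_input("`mu_oct` must be positive")
  if (any(mu_hats < 0)) stop_input("`mu_hats` must be non-negative")
  exp(-length(mu_hats) * log(mu_oct) - sum(mu_hats) / mu_oct)
}

#' Prior density of the attenuation coefficient
#'
#' Gaussian density with mean `layer_mean` and variance
#' `zeta * layer_mean`, as printed (not renormalized for positivity).
#'
#' @param mu Attenuation value(s) at which to evaluate (mm^-1).
#' @param prior A [prior_spec()].
#' @return Density value(s), units mm.
#' @export
prior_density <- function(mu, prior) {
  stopifnot(inherits(prior, "oct_prior"))
  dnorm(mu, prior$layer_mean, sqrt(prior$zeta * prior$layer_mean))
}

default_grid <- function(prior, mu_hats, n_grid) {
  lo <- max(1e-6, prior$layer_mean * 1e-4)
  hi <- prior$layer_mean + 10 * sqrt(prior$zeta * prior$layer_mean) +
    max(mu_hats)
  exp(seq(log(lo), log(hi), length.out = n_grid))
}

#' Normalized posterior of the attenuation coefficient at one voxel
#'
#' Tabulates `likelihood_multi(mu_hats, mu) * prior_density(mu, prior)`
#' on a log-spaced grid and normalizes it with the trapezoid rule.  The
#' log-spaced grid resolves the near-origin likelihood spike that appears
#' for small DR estimates (and makes the posterior bimodal) while still
#' covering the prior bulk; evaluation is done in the log domain with
#' max-subtraction before exponentiation.
#'
#' The default grid has 4096 points on `[mu_lo, mu_hi]` with
#' `mu_lo = max(1e-6, layer_mean * 1e-4)` and
#' `mu_hi = layer_mean + 10 * sqrt(zeta * layer_mean) + max(mu_hats)`.
#' When every estimate is exactly zero the likelihood `1/mu` is not
#' integrable near the origin and the result depends on `mu_lo`; a
#' warning is issued.
#'
#' @param mu_hats Vector of k >= 1 observed DR estimates (mm^-1, >= 0).
#' @param prior A [prior_spec()].
#' @param n_grid Number of grid points (default 4096).
#' @param mu_lo,mu_hi Optional grid bounds (mm^-1) overriding the
#'   defaults.
#' @return An object of class `oct_posterior` with fields `mu_grid`,
#'   `density` (trapezoid-normalized), `dr_estimates` and `prior`.
#' @examples
#' pr <- prior_spec(0.4, 6.87e-2)
#' po <- posterior(1.3, pr)
#' posterior_mean(po)
#' @export
posterior <- function(mu_hats, prior, n_grid = 4096,
                      mu_lo = NULL, mu_hi = NULL) {
  stopifnot(inherits(prior, "oct_prior"))
  if (length(mu_hats) < 1) stop_input("need at least one DR estimate")
  if (any(mu_hats < 0)) stop_input("`mu_hats` must be non-negative")
  if (all(mu_hats == 0))
    warning("all DR estimates are zero: the posterior is improper near the ",
            "origin and the result depends on the grid floor `mu_lo`",
            call. = FALSE)
  g <- default_grid(prior, mu_hats, n_grid)
  if (!is.null(mu_lo)) g <- g[g >= mu_lo] |> (\(x) unique(c(mu_lo, x)))()
  if (!is.null(mu_hi)) g <- g[g <= mu_hi] |> (\(x) unique(c(x, mu_hi)))()
  if (length(g) < 8) stop_input("posterior grid has fewer than 8 points")
  ld <- -length(mu_hats) * log(g) - sum(mu_hats) / g +
    dnorm(g, prior$layer_mean, sqrt(prior$zeta * prior$layer_mean),
          log = TRUE)
  d <- exp(ld - max(ld))
  d <- d / trapz(g, d)
  structure(list(mu_grid = g, density = d, dr_estimates = mu_hats,
                 prior = prior),
            class = "oct_posterior")
}

#' @export
print.oct_posterior <- function(x, ...) {
  cat(sprintf(
    "<oct_posterior> %d-point grid on [%.4g, %.4g] mm^-1; k = %d estimate(s)\n",
    length(x$mu_grid), min(x$mu_grid), max(x$mu_grid),
    length(x$dr_estimates)))
  cat(sprintf("  posterior mean %.4g mm^-1, sd %.4g mm^-1\n",
              posterior_mean(x), sqrt(posterior_variance(x))))
  invisible(x)
}

#' Posterior mean of the attenuation coefficient
#'
#' Trapezoid integral of `mu * density` over the tabulated grid.  This is
#' the package's default single-number estimator: unlike the posterior
#' mode, it is stable when small DR estimates make the posterior bimodal,
#' because the narrow near-origin peak carries little probability mass.
#'
#' @param post An `oct_posterior` from [posterior()].
#' @return Attenuation (mm^-1).
#' @export
posterior_mean <- function(post) {
  stopifnot(inherits(post, "oct_posterior"))
  trapz(post$mu_grid, post$mu_grid * post$density)
}

#' Posterior mode (maximum a posteriori)
#'
#' Grid argmax of the tabulated density, refined by a quadratic fit
#' through the three bracketing points.  Retained for comparison with the
#' posterior mean; for small DR estimates the mode can sit on a narrow
#' near-origin peak and misrepresent the distribution.  A boundary argmax
#' triggers a warning (possible truncated mode) and is returned
#' unrefined.
#'
#' @param post An `oct_posterior` from [posterior()].
#' @return Attenuation (mm^-1).
#' @export
posterior_map <- function(post) {
  stopifnot(inherits(post, "oct_posterior"))
  g <- post$mu_grid
  d <- post$density
  i <- which.max(d)
  if (i == 1 || i == length(g)) {
    warning("posterior mode lies on the grid boundary; the true mode may be ",
            "truncated", call. = FALSE)
    return(g[i])
  }
  # vertex of the parabola through the three bracketing points
  x1 <- g[i - 1]; x2 <- g[i]; x3 <- g[i + 1]
  y1 <- d[i - 1]; y2 <- d[i]; y3 <- d[i + 1]
  denom <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (denom == 0) return(g[i])
  x2 - 0.5 * ((x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)) / denom
}

#' Posterior variance of the attenuation coefficient
#'
#' Trapezoid integral of `(mu - posterior_mean)^2 * density`; quantifies
#' the voxelwise uncertainty left after conditioning on the DR estimates.
#'
#' @param post An `oct_posterior` from [posterior()].
#' @return Variance (mm^-2).
#' @export
posterior_variance <- function(post) {
  stopifnot(inherits(post, "oct_posterior"))
  m <- posterior_mean(post)
  trapz(post$mu_grid, (post$mu_grid - m)^2 * post$density)
}

#' Posterior-mean attenuation map from a DR map
#'
#' Treats voxels as independent, so the joint posterior over the scan
#' factorizes and the posterior mean can be computed voxel by voxel from
#' each single DR estimate.  All admissible voxels share one log-spaced
#' grid (its upper end covers the largest estimate in the map), and the
#' computation is chunked so that B-scan-sized maps stay within memory.
#' Masked or undefined voxels carry `NA` in the output.
#'
#' @param dr_map An `oct_dr_map` with at least one admissible voxel.
#' @param prior A [prior_spec()]; typically built from [layer_mean()] of
#'   the same map and a physics- or config-supplied `zeta`.
#' @param n_grid Number of quadrature points (default 4096).
#' @param chunk Number of voxels processed per block (default 2048).
#' @return An [attenuation_profile()] with `NA` at non-admissible voxels.
#' @export
estimate_map <- function(dr_map, prior, n_grid = 4096, chunk = 2048) {
  stopifnot(inherits(dr_map, "oct_dr_map"), inherits(prior, "oct_prior"))
  mask <- dr_map$admissible_mask
  mu_hats <- dr_map$estimates[mask]
  if (length(mu_hats) == 0) stop_input("no admissible voxels in `dr_map`")
  g <- default_grid(prior, max(mu_hats), n_grid)
  lp <- -log(g) + dnorm(g, prior$layer_mean,
                        sqrt(prior$zeta * prior$layer_mean), log = TRUE)
  w <- trapz_weights(g)
  wg <- w * g
  inv_g <- 1 / g
  means <- numeric(length(mu_hats))
  for (start in seq(1, length(mu_hats), by = chunk)) {
    idx <- start:min(start + chunk - 1, length(mu_hats))
    ll <- lp - outer(inv_g, mu_hats[idx])       # n_grid x |idx|
    ll <- sweep(ll, 2, apply(ll, 2, max))
    dens <- exp(ll)
    means[idx] <- as.numeric(crossprod(dens, wg) / crossprod(dens, w))
  }
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  out[mask] <- means
  attenuation_profile(out, dr_map$geometry, allow_na = TRUE)
}
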