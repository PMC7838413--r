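#' Speckle-free mean OCT signal of an attenuation map
#'
#' Evaluates the discrete single-scattering decay model per A-line: at
#' depth pixel N the mean intensity is
#' `I_inc * beta_NA * mu(N) * exp(-2 * sum_{i=1..N} mu(i) * dz)`,
#' where the cumulative attenuation includes the pixel's own contribution.
#' The model assumes negligible absorption, a constant back-scattered
#' fraction, and a signal already calibrated for confocal and roll-off
#' effects.
#'
#' @param profile An [attenuation_profile()] (no `NA` values).
#' @return An [scan_field()] with `is_realization = FALSE`.
#' @examples
#' g <- acquisition_geometry(0.0068, 0.022, 3.4)
#' p <- attenuation_profile(matrix(2, g$n_depth, 1), g)
#' s <- mean_signal(p)
#' s$intensities[1, 1]  # 0.3 * 1e7 * 2 * exp(-2 * 2 * 0.0068)
#' @export
mean_signal <- function(profile) {
  stopifnot(inherits(profile, "oct_profile"))
  if (anyNA(profile$values))
    stop_input("profile contains NA voxels; mean_signal needs a complete map")
  g <- profile$geometry
  mu <- profile$values
  cum <- apply(mu * g$axial_pitch, 2, cumsum)
  cum <- matrix(cum, nrow = nrow(mu))
  intens <- g$incident_intensity * g$backscatter_fraction * mu * exp(-2 * cum)
  scan_field(intens, g, is_realization = FALSE)
}

#' Draw one speckled realization of a mean scan
#'
#' Under fully developed speckle the measured amplitude is Rayleigh
#' distributed, so the intensity at each voxel is an independent
#' exponential variate whose mean is the speckle-free model intensity.
#' Voxels with zero mean intensity stay exactly zero.  Draws are taken
#' column by column (A-line by A-line) from a single seeded stream, so a
#' given `(mean_scan, seed)` pair is bit-reproducible.
#'
#' @param mean_scan A mean-signal [scan_field()] (`is_realization = FALSE`).
#' @param seed Integer seed; recorded in the returned object.
#' @return A [scan_field()] with `is_realization = TRUE`.
#' @export
speckle_sample <- function(mean_scan, seed) {
  stopifnot(inherits(mean_scan, "oct_scan"))
  if (mean_scan$is_realization)
    stop_input("`mean_scan` is already a speckled realization")
  m <- mean_scan$intensities
  draws <- with_seed(seed, rexp(length(m)))
  intens <- m * matrix(draws, nrow = nrow(m))   # Exp(mean m) = m * Exp(1)
  scan_field(intens, mean_scan$geometry, is_realization = TRUE, seed = seed)
}

#' Sample a ground-truth attenuation map from the prior
#'
#' Draws i.i.d. voxel values from the Gaussian scatterer-count prior
#' (mean `layer_mean`, variance `zeta * layer_mean`), truncated to
#' non-negative values by rejection.  Used to generate ground truth for
#' end-to-end parameter-recovery experiments.
#'
#' @param prior A [prior_spec()].
#' @param geometry An [acquisition_geometry()].
#' @param seed Integer seed.
#' @param n_lateral Number of A-lines to draw (default 1).
#' @return An [attenuation_profile()].
#' @export
sample_prior_map <- function(prior, geometry, seed, n_lateral = 1) {
  stopifnot(inherits(prior, "oct_prior"), inherits(geometry, "oct_geometry"))
  n <- geometry$n_depth * n_lateral
  sd <- sqrt(prior$zeta * prior$layer_mean)
  v <- with_seed(seed, {
    x <- rnorm(n, prior$layer_mean, sd)
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), prior$layer_mean, sd)
    x
  })
  attenuation_profile(matrix(v, nrow = geometry$n_depth), geometry)
}
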