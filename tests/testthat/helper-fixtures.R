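# small geometries and scans shared across tests

tiny_geometry <- function(n_depth = 10, axial_pitch = 0.01) {
  acquisition_geometry(axial_pitch = axial_pitch, lateral_pitch = 0.02,
                       depth_extent = axial_pitch * (n_depth + 0.5),
                       incident_intensity = 1e7,
                       backscatter_fraction = 0.3)
}

standard_bscan_geometry <- function() {
  # 500 depths of 0.0068 mm over 3.4 mm, 0.022 mm lateral pitch
  acquisition_geometry(axial_pitch = 0.0068, lateral_pitch = 0.022,
                       depth_extent = 3.4, incident_intensity = 1e7,
                       backscatter_fraction = 0.3)
}

constant_profile <- function(mu, geometry, n_lines = 1) {
  attenuation_profile(matrix(mu, geometry$n_depth, n_lines), geometry)
}

# closed-form DR value for a noiseless constant-mu signal with a long tail
dr_closed_form <- function(mu, dz) (exp(2 * mu * dz) - 1) / (2 * dz)

count_local_maxima <- function(density) {
  sum(diff(sign(diff(density))) == -2)
}

# importance-sampling oracle for posterior mean / variance: proposal is the
# positivity-truncated prior, weights are the (multi-)likelihood
is_posterior_oracle <- function(mu_hats, prior, n = 1e5, seed = 1) {
  sd <- sqrt(prior$zeta * prior$layer_mean)
  x <- withr::with_seed(seed, {
    x <- rnorm(n, prior$layer_mean, sd)
    while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), prior$layer_mean, sd)
    x
  })
  lw <- -length(mu_hats) * log(x) - sum(mu_hats) / x
  w <- exp(lw - max(lw))
  est_mean <- sum(w * x) / sum(w)
  e_mean <- w * (x - est_mean) / mean(w)
  h <- (x - est_mean)^2
  est_var <- sum(w * h) / sum(w)
  e_var <- w * (h - est_var) / mean(w)
  list(mean = est_mean, mean_se = stats::sd(e_mean) / sqrt(n),
       var = est_var, var_se = stats::sd(e_var) / sqrt(n))
}
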