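#' Reference acquisition geometries
#'
#' `default_bscan_geometry()` is the package's homogeneous-validation
#' geometry: 500 depths of 0.0068 mm (3.4 mm deep), 0.022 mm lateral
#' pitch, incident intensity 1e7, back-scatter fraction 0.3.
#' `deep_scan_geometry()` is the deep parameter-recovery geometry: by
#' default 2000 depths of 0.0068 mm (13.6 mm) with 0.02 mm lateral pitch.
#'
#' @param n_depth,axial_pitch,lateral_pitch Overrides for the deep
#'   geometry (mm).
#' @return An [acquisition_geometry()].
#' @export
default_bscan_geometry <- function() {
  acquisition_geometry(axial_pitch = 0.0068, lateral_pitch = 0.022,
                       depth_extent = 3.4, incident_intensity = 1e7,
                       backscatter_fraction = 0.3)
}

#' @rdname default_bscan_geometry
#' @export
deep_scan_geometry <- function(n_depth = 2000, axial_pitch = 0.0068,
                               lateral_pitch = 0.02) {
  # depth_extent padded by half a pixel so floating-point division cannot
  # drop the last depth row
  acquisition_geometry(axial_pitch = axial_pitch,
                       lateral_pitch = lateral_pitch,
                       depth_extent = axial_pitch * (n_depth + 0.5),
                       incident_intensity = 1e7,
                       backscatter_fraction = 0.3)
}

# tiny polynomial rolling hash of a deparsed object, for report provenance
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

report_meta <- function(params, seed) {
  list(seed = seed, params = params, config_hash = config_hash(params),
       octbayes_version = as.character(utils::packageVersion("octbayes")))
}

new_report <- function(kind, fields, params, seed) {
  structure(c(list(kind = kind), fields, list(meta = report_meta(params, seed))),
            class = "oct_experiment_report")
}

#' @export
print.oct_experiment_report <- function(x, ...) {
  cat(sprintf("<oct_experiment_report> %s (seed %s, config %s)\n",
              x$kind, format(x$meta$seed), x$meta$config_hash))
  for (nm in setdiff(names(x), c("kind", "meta"))) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1) cat(sprintf("  %s: %.6g\n", nm, v))
    else if (is.data.frame(v)) cat(sprintf("  %s: <%d x %d table>\n",
                                           nm, nrow(v), ncol(v)))
    else if (is.numeric(v)) cat(sprintf("  %s: numeric[%d]\n", nm, length(v)))
  }
  invisible(x)
}

#' Simulate a B-scan (mean signal plus one speckled realization)
#'
#' @param geometry An [acquisition_geometry()]; default is the package's
#'   homogeneous-validation geometry (0.0068 mm axial pitch, 3.4 mm deep,
#'   0.022 mm lateral pitch, incident intensity 1e7, back-scatter
#'   fraction 0.3).
#' @param truth Either a single attenuation (mm^-1), a depth profile
#'   vector, a full matrix, an [attenuation_profile()], or a
#'   [prior_spec()] (in which case the ground truth is sampled from the
#'   prior).
#' @param n_lines Number of A-lines when `truth` is scalar, vector or a
#'   prior.
#' @param seed Integer seed for the speckle draw (and the prior draw when
#'   `truth` is a prior).
#' @return A list with `profile`, `mean_scan` and `speckled`.
#' @export
simulate_bscan <- function(truth, geometry = default_bscan_geometry(),
                           n_lines = 1, seed = 1) {
  profile <-
    if (inherits(truth, "oct_profile")) truth
    else if (inherits(truth, "oct_prior"))
      sample_prior_map(truth, geometry, seed = seed, n_lateral = n_lines)
    else if (is.matrix(truth)) attenuation_profile(truth, geometry)
    else attenuation_profile(
      matrix(truth, nrow = geometry$n_depth, ncol = n_lines), geometry)
  mean_scan <- mean_signal(profile)
  speckled <- speckle_sample(mean_scan, seed = seed)
  list(profile = profile, mean_scan = mean_scan, speckled = speckled)
}

#' Homogeneous-medium validation of the speckle likelihood
#'
#' Simulates a homogeneous speckled B-scan, runs the DR estimator,
#' discards the deepest rows, and checks the exponential law of the
#' pooled admissible estimates: the maximum-likelihood exponential fit
#' (the sample mean -- the canonical, bin-free estimator), a
#' Kolmogorov-Smirnov statistic against the exponential with the true
#' mean on a seeded subsample, and the analytic per-depth coefficient of
#' variation of the DR denominator, optionally compared with its
#' empirical value across speckle replicates.
#'
#' @param mu True attenuation coefficient (mm^-1).
#' @param geometry An [acquisition_geometry()].
#' @param n_lines Number of A-lines in the B-scan.
#' @param truncation_fraction Deep-row fraction to discard.
#' @param seed Integer seed.
#' @param ks_sample Subsample size for the KS statistic (the pooled count
#'   is so large that the test would otherwise detect the estimator's
#'   small discretization bias rather than the exponential shape).
#' @param cv_replicates If > 0, also simulate this many independent
#'   speckled A-lines and report the empirical per-depth C_v of the DR
#'   denominator next to the analytic value.
#' @return An `oct_experiment_report` with `fitted_rate_mm1` (ML
#'   exponential mean), `fit_se` (nominal i.i.d. standard error),
#'   `pooled_n`, `ks_statistic`, `ks_p_value`, `cv_analytic` (per
#'   admissible depth) and, when requested, `cv_empirical` and
#'   `cv_empirical_se`.
#' @export
run_homogeneous_validation <- function(mu = 2, geometry = default_bscan_geometry(),
                                       n_lines = 1000,
                                       truncation_fraction = 0.3,
                                       seed = 1, ks_sample = 2000,
                                       cv_replicates = 0) {
  sim <- simulate_bscan(mu, geometry, n_lines = n_lines, seed = seed)
  dr <- dr_estimate(sim$speckled, truncation_fraction)
  pooled <- dr$estimates[dr$admissible_mask]
  fitted <- mean(pooled)                      # ML fit of the exponential mean
  ks_idx <- with_seed(seed + 1L,
                      sample.int(length(pooled), min(ks_sample, length(pooled))))
  ks <- suppressWarnings(ks.test(pooled[ks_idx], "pexp", rate = 1 / mu))
  one_line <- scan_field(sim$mean_scan$intensities[, 1], geometry)
  stats <- denominator_stats(one_line)
  adm <- seq_len(floor((1 - truncation_fraction) * geometry$n_depth))
  fields <- list(fitted_rate_mm1 = fitted,
                 fit_se = stats::sd(pooled) / sqrt(length(pooled)),
                 pooled_n = length(pooled),
                 ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value,
                 cv_analytic = stats$cv[adm, 1])
  if (cv_replicates > 0) {
    wide <- scan_field(
      matrix(sim$mean_scan$intensities[, 1], geometry$n_depth,
             cv_replicates),
      geometry)
    spk <- speckle_sample(wide, seed = seed + 2L)
    I <- spk$intensities
    D <- 2 * geometry$axial_pitch * (rev_colcumsum(I) - I)
    emp_mean <- rowMeans(D[adm, , drop = FALSE])
    emp_sd <- apply(D[adm, , drop = FALSE], 1, stats::sd)
    fields$cv_empirical <- emp_sd / emp_mean
    # asymptotic se of a sample C_v for a near-Gaussian sum
    fields$cv_empirical_se <- fields$cv_empirical *
      sqrt(1 / (2 * (cv_replicates - 1)) +
             fields$cv_empirical^2 / cv_replicates)
  }
  new_report("homogeneous_validation", fields,
             list(mu = mu, geometry = unclass(geometry), n_lines = n_lines,
                  truncation_fraction = truncation_fraction,
                  ks_sample = ks_sample, cv_replicates = cv_replicates),
             seed)
}

recovery_errors <- function(truth, dr, post_profile) {
  mask <- dr$admissible_mask
  c(err_dr = mean(abs(dr$estimates[mask] - truth$values[mask])),
    err_post = mean(abs(post_profile$values[mask] - truth$values[mask])))
}

#' Parameter recovery with a prior-sampled ground truth
#'
#' Repeats, for each replicate: sample a ground-truth attenuation map
#' from the prior, simulate a speckled scan, run the DR estimator,
#' truncate the deepest rows, build the working prior from the layer mean
#' of the truncated DR estimates (the true layer mean is treated as
#' unknown) together with the supplied `zeta`, and compute the
#' posterior-mean map.  Voxelwise absolute (L2) errors of the raw DR map
#' and the posterior-mean map against the truth are averaged over the
#' admissible voxels.
#'
#' The default `zeta` follows from the default scattering cross-section
#' 1e-6 mm^2 divided by the voxel volume of the default geometry.
#'
#' @param layer_mean True layer-mean attenuation (mm^-1).
#' @param zeta Prior width parameter (mm^-1).
#' @param geometry An [acquisition_geometry()]; the default is the deep
#'   recovery geometry (2000 depths of 0.0068 mm, lateral pitch 0.02 mm).
#' @param n_lines A-lines per replicate (default 1).
#' @param n_replicates Number of seeded replicates.
#' @param truncation_fraction Deep-row fraction to discard.
#' @param seed Root seed; replicate r uses `seed + r - 1`.
#' @param n_grid Posterior quadrature points per voxel.
#' @return An `oct_experiment_report` with a per-replicate `table`
#'   (`err_dr`, `err_post`, `layer_mean_hat`), `frac_posterior_wins`,
#'   `mean_err_dr`, `mean_err_post` and their standard errors.
#' @export
run_prior_recovery <- function(layer_mean = 2,
                               zeta = NULL,
                               geometry = deep_scan_geometry(),
                               n_lines = 1, n_replicates = 50,
                               truncation_fraction = 0.3,
                               seed = 1, n_grid = 4096) {
  if (is.null(zeta)) {
    vox <- voxel_geometry(c(geometry$axial_pitch, geometry$lateral_pitch,
                            geometry$lateral_pitch))
    zeta <- zeta_from_geometry(1e-6, vox)
  }
  # the working prior is rebuilt per replicate from the data; its small
  # negative-mass truncation is expected, so the constructor warning is
  # silenced here
  prior_true <- suppressWarnings(prior_spec(layer_mean, zeta))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- seed + r - 1L
    truth <- sample_prior_map(prior_true, geometry, seed = s,
                              n_lateral = n_lines)
    spk <- speckle_sample(mean_signal(truth), seed = s + 500000L)
    dr <- dr_estimate(spk, truncation_fraction)
    lm_hat <- layer_mean(dr)
    prior_hat <- suppressWarnings(prior_spec(lm_hat, zeta))
    post <- estimate_map(dr, prior_hat, n_grid = n_grid)
    e <- recovery_errors(truth, dr, post)
    rows[[r]] <- data.frame(replicate = r, err_dr = e[["err_dr"]],
                            err_post = e[["err_post"]],
                            layer_mean_hat = lm_hat)
  }
  tab <- do.call(rbind, rows)
  fields <- list(
    table = tab,
    frac_posterior_wins = mean(tab$err_post < tab$err_dr),
    mean_err_dr = mean(tab$err_dr),
    mean_err_post = mean(tab$err_post),
    se_err_dr = stats::sd(tab$err_dr) / sqrt(n_replicates),
    se_err_post = stats::sd(tab$err_post) / sqrt(n_replicates))
  new_report("prior_recovery", fields,
             list(layer_mean = layer_mean, zeta = zeta,
                  geometry = unclass(geometry), n_lines = n_lines,
                  n_replicates = n_replicates,
                  truncation_fraction = truncation_fraction,
                  n_grid = n_grid),
             seed)
}

#' Error sweep over layer mean and prior width
#'
#' For every combination of `mean_grid` and `zeta_grid`, simulates a
#' single A-scan with a prior-sampled ground truth, runs the DR
#' estimator, discards the deepest rows, computes the posterior-mean map,
#' and records the averaged voxelwise absolute error of both estimators.
#' With the default 2000-depth A-scan and 30% truncation each point
#' averages over 1400 admissible pixels.
#'
#' @param mean_grid Layer-mean values to sweep (mm^-1).
#' @param zeta_grid Prior width values to sweep (mm^-1).
#' @param n_depth Depth pixels per A-scan.
#' @param truncation_fraction Deep-row fraction to discard.
#' @param seed Root seed; each grid point derives its own sub-seed.
#' @param n_grid Posterior quadrature points.
#' @return An `oct_experiment_report` whose `table` has one row per
#'   `(layer_mean, zeta)` point with `err_dr`, `err_post`, `n_pixels`.
#' @export
run_error_sweep <- function(mean_grid = c(0.5, 1, 2, 4),
                            zeta_grid = c(1e-3, 1e-2, 1e-1),
                            n_depth = 2000, truncation_fraction = 0.3,
                            seed = 1, n_grid = 4096) {
  geometry <- deep_scan_geometry(n_depth = n_depth)
  grid <- expand.grid(layer_mean = mean_grid, zeta = zeta_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- grid$layer_mean[i]; z <- grid$zeta[i]
    s <- seed + i - 1L
    prior_true <- suppressWarnings(prior_spec(m, z))
    truth <- sample_prior_map(prior_true, geometry, seed = s)
    spk <- speckle_sample(mean_signal(truth), seed = s + 900000L)
    dr <- dr_estimate(spk, truncation_fraction)
    prior_hat <- suppressWarnings(prior_spec(layer_mean(dr), z))
    post <- estimate_map(dr, prior_hat, n_grid = n_grid)
    e <- recovery_errors(truth, dr, post)
    rows[[i]] <- data.frame(layer_mean = m, zeta = z,
                            err_dr = e[["err_dr"]],
                            err_post = e[["err_post"]],
                            n_pixels = sum(dr$admissible_mask))
  }
  new_report("error_sweep", list(table = do.call(rbind, rows)),
             list(mean_grid = mean_grid, zeta_grid = zeta_grid,
                  n_depth = n_depth,
                  truncation_fraction = truncation_fraction,
                  n_grid = n_grid),
             seed)
}

#' Lateral averaging of a scan
#'
#' Averages intensities over non-overlapping lateral windows; trailing
#' A-lines that do not fill a window are dropped.  Lateral averaging is
#' the traditional speckle remedy and is provided as a comparison
#' baseline for the posterior-mean estimator, not as a recommended
#' method.
#'
#' @param scan An [scan_field()].
#' @param window Window width in A-lines (>= 1, <= lateral extent).
#' @return A [scan_field()] with `floor(ncol / window)` columns.
#' @export
lateral_average <- function(scan, window) {
  stopifnot(inherits(scan, "oct_scan"))
  L <- ncol(scan$intensities)
  if (window < 1 || window > L)
    stop_input("`window` must lie in [1, ", L, "]")
  window <- as.integer(window)
  n_out <- L %/% window
  I <- scan$intensities[, seq_len(n_out * window), drop = FALSE]
  dim(I) <- c(nrow(I) * window, n_out)
  # average each consecutive group of `window` columns
  out <- sapply(seq_len(n_out), function(j) {
    rowMeans(matrix(I[, j], nrow = nrow(scan$intensities)))
  })
  scan_field(matrix(out, nrow = nrow(scan$intensities)), scan$geometry,
             is_realization = scan$is_realization, seed = scan$seed)
}

#' Lateral-averaging DR baseline
#'
#' Averages the scan laterally with [lateral_average()] and then applies
#' [dr_estimate()].
#'
#' @inheritParams lateral_average
#' @inheritParams dr_estimate
#' @return An `oct_dr_map` on the averaged scan.
#' @export
lateral_average_baseline <- function(scan, window, truncation_fraction = 0.3,
                                     tail_mode = c("none", "liu"),
                                     mu_ref = NULL) {
  dr_estimate(lateral_average(scan, window), truncation_fraction,
              tail_mode = tail_mode, mu_ref = mu_ref)
}

#' Read a workflow configuration file
#'
#' Reads a JSON or YAML configuration describing a simulation run and
#' fills in defaults.  Recognized top-level entries: `geometry`
#' (`axial_pitch`, `lateral_pitch`, `depth_extent`,
#' `incident_intensity`, `backscatter_fraction`), `truth` (`type` one of
#' `"constant"`, `"layered"`, `"prior"` with `mu`, `layers` or
#' `layer_mean`/`zeta`), `n_lines`, `seeds`, `truncation_fraction`,
#' `tail_mode`, `n_grid` and `out_dir`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated config list with classes resolved: `$geometry` is
#'   an [acquisition_geometry()] and `$truth_profile(geometry, seed)` a
#'   function materializing the ground truth.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- list(
    geometry = list(axial_pitch = 0.0068, lateral_pitch = 0.022,
                    depth_extent = 3.4, incident_intensity = 1e7,
                    backscatter_fraction = 0.3),
    truth = list(type = "constant", mu = 2.0),
    n_lines = 1000, seeds = 1L, truncation_fraction = 0.3,
    tail_mode = "none", n_grid = 4096, out_dir = ".")
  cfg <- modifyList(defaults, raw)
  if (length(cfg$seeds) < 1) stop_input("config must list at least one seed")
  g <- do.call(acquisition_geometry, cfg$geometry)
  cfg$geometry <- g
  tr <- cfg$truth
  cfg$truth_profile <- switch(
    tr$type,
    constant = function(geometry, seed)
      attenuation_profile(matrix(tr$mu, geometry$n_depth, cfg$n_lines),
                          geometry),
    layered = function(geometry, seed) {
      mu <- unlist(mapply(
        function(m, th) rep(m, round(th / geometry$axial_pitch)),
        vapply(tr$layers, `[[`, 0, "mu"),
        vapply(tr$layers, `[[`, 0, "thickness"), SIMPLIFY = FALSE))
      mu <- rep_len(mu, geometry$n_depth)
      attenuation_profile(matrix(mu, geometry$n_depth, cfg$n_lines),
                          geometry)
    },
    prior = function(geometry, seed)
      sample_prior_map(suppressWarnings(prior_spec(tr$layer_mean, tr$zeta)),
                       geometry, seed = seed, n_lateral = cfg$n_lines),
    stop_input("unknown truth type: ", tr$type))
  cfg
}
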