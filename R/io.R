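#' @section File formats:
#' Image-like objects are serialized as a single-page TIFF (depth = rows,
#' lateral = columns) plus a JSON sidecar `<path>.json`.  The TIFF library
#' stores samples scaled to \[0, 1\], so values are divided by a `scale`
#' factor recorded in the sidecar and multiplied back on read (32-bit
#' samples give about 9 significant digits relative to the scan maximum).
#' `NA` voxels (masked estimates) are written as zero and their indices
#' recorded in the sidecar.
#' @name octbayes-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

write_grid_tiff <- function(values, path, meta) {
  na_idx <- which(is.na(values))
  v <- values
  v[na_idx] <- 0
  scale <- max(v, 1e-300)
  meta$scale <- scale
  meta$n_depth <- nrow(values)
  meta$n_lateral <- ncol(values)
  meta$na_indices <- na_idx
  meta$octbayes_version <- as.character(utils::packageVersion("octbayes"))
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_grid_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  v <- tiff::readTIFF(path) * meta$scale
  v <- matrix(v, nrow = meta$n_depth)
  if (length(meta$na_indices) > 0) v[meta$na_indices] <- NA_real_
  list(values = v, meta = meta)
}

geometry_meta <- function(g) {
  list(axial_pitch = g$axial_pitch, lateral_pitch = g$lateral_pitch,
       depth_extent = g$depth_extent,
       incident_intensity = g$incident_intensity,
       backscatter_fraction = g$backscatter_fraction)
}

geometry_from_meta <- function(meta) {
  acquisition_geometry(meta$axial_pitch, meta$lateral_pitch,
                       meta$depth_extent, meta$incident_intensity,
                       meta$backscatter_fraction)
}

#' Write / read a scan field as TIFF + JSON sidecar
#'
#' @param scan An [scan_field()].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `write_scan_field()` returns `path` invisibly;
#'   `read_scan_field()` returns the reconstructed [scan_field()].
#' @export
write_scan_field <- function(scan, path) {
  stopifnot(inherits(scan, "oct_scan"))
  meta <- c(list(type = "scan_field", is_realization = scan$is_realization,
                 seed = scan$seed), geometry_meta(scan$geometry))
  write_grid_tiff(scan$intensities, path, meta)
}

#' @rdname write_scan_field
#' @export
read_scan_field <- function(path) {
  r <- read_grid_tiff(path)
  scan_field(r$values, geometry_from_meta(r$meta),
             is_realization = isTRUE(r$meta$is_realization),
             seed = r$meta$seed)
}

#' Write / read an attenuation profile as TIFF + JSON sidecar
#'
#' @param profile An [attenuation_profile()] (may contain `NA` voxels,
#'   e.g. the output of [estimate_map()]).
#' @param path Output TIFF path.
#' @return `write_attenuation_profile()` returns `path` invisibly;
#'   `read_attenuation_profile()` the reconstructed profile.
#' @export
write_attenuation_profile <- function(profile, path) {
  stopifnot(inherits(profile, "oct_profile"))
  meta <- c(list(type = "attenuation_profile"),
            geometry_meta(profile$geometry))
  write_grid_tiff(profile$values, path, meta)
}

#' @rdname write_attenuation_profile
#' @export
read_attenuation_profile <- function(path) {
  r <- read_grid_tiff(path)
  attenuation_profile(r$values, geometry_from_meta(r$meta), allow_na = TRUE)
}

#' Write / read a DR map as TIFF + JSON sidecar
#'
#' The sidecar records `truncation_fraction` and `tail_mode`; the
#' admissible mask is reconstructed from them plus the `NA` voxel list.
#'
#' @param dr_map An `oct_dr_map` from [dr_estimate()].
#' @param path Output TIFF path.
#' @return `write_dr_map()` returns `path` invisibly; `read_dr_map()` the
#'   reconstructed map.
#' @export
write_dr_map <- function(dr_map, path) {
  stopifnot(inherits(dr_map, "oct_dr_map"))
  meta <- c(list(type = "dr_map",
                 truncation_fraction = dr_map$truncation_fraction,
                 tail_mode = dr_map$tail_mode),
            geometry_meta(dr_map$geometry))
  write_grid_tiff(dr_map$estimates, path, meta)
}

#' @rdname write_dr_map
#' @export
read_dr_map <- function(path) {
  r <- read_grid_tiff(path)
  est <- r$values
  M <- nrow(est)
  n_keep <- floor((1 - r$meta$truncation_fraction) * M)
  mask <- matrix(FALSE, M, ncol(est))
  if (n_keep >= 1) mask[seq_len(n_keep), ] <- TRUE
  mask[M, ] <- FALSE
  mask[is.na(est)] <- FALSE
  structure(list(estimates = est, admissible_mask = mask,
                 truncation_fraction = r$meta$truncation_fraction,
                 tail_mode = r$meta$tail_mode,
                 geometry = geometry_from_meta(r$meta)),
            class = "oct_dr_map")
}

#' CSV exports
#'
#' Small plain-text exports: a scan or profile as a bare matrix, a
#' posterior as a two-column `(mu, density)` table, and per-depth
#' denominator statistics for one A-line.
#'
#' @param scan,post,stats Objects to export.
#' @param path Output CSV path.
#' @param column A-line (column) to export for denominator statistics.
#' @return The path, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "oct_scan") || inherits(scan, "oct_profile"))
  m <- if (inherits(scan, "oct_scan")) scan$intensities else scan$values
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_posterior_csv <- function(post, path) {
  stopifnot(inherits(post, "oct_posterior"))
  write.csv(data.frame(mu = post$mu_grid, density = post$density),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
write_denominator_stats_csv <- function(stats, path, column = 1) {
  stopifnot(inherits(stats, "oct_denominator_stats"))
  dz <- stats$geometry$axial_pitch
  n <- nrow(stats$mean)
  write.csv(data.frame(depth_index = seq_len(n),
                       depth_mm = seq_len(n) * dz,
                       mean = stats$mean[, column],
                       sd = stats$sd[, column],
                       cv = stats$cv[, column]),
            path, row.names = FALSE)
  invisible(path)
}
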