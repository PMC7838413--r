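#' Acquisition geometry of an OCT scan
#'
#' Bundles the voxel pitches, depth extent and optical constants of a
#' (simulated or measured) OCT acquisition.  The number of depth pixels is
#' `floor(depth_extent / axial_pitch)`.
#'
#' @param axial_pitch Axial voxel pitch in mm (> 0).
#' @param lateral_pitch Lateral voxel pitch in mm (> 0).
#' @param depth_extent Imaging depth in mm; must give at least 2 depth
#'   pixels.
#' @param incident_intensity Incident intensity in arbitrary power units
#'   (> 0).  The depth-resolved estimator is scale invariant, so these
#'   units never need calibration.
#' @param backscatter_fraction Fraction of the attenuated light
#'   back-scattered into the detection numerical aperture, in (0, 1].
#'   Assumed constant through the medium.
#'
#' @return An object of class `oct_geometry` with fields `axial_pitch`,
#'   `lateral_pitch`, `depth_extent`, `incident_intensity`,
#'   `backscatter_fraction` and `n_depth`.
#' @examples
#' g <- acquisition_geometry(0.0068, 0.022, 3.4,
#'                           incident_intensity = 1e7,
#'                           backscatter_fraction = 0.3)
#' g$n_depth  # 500
#' @export
acquisition_geometry <- function(axial_pitch, lateral_pitch, depth_extent,
                                 incident_intensity = 1e7,
                                 backscatter_fraction = 0.3) {
  if (!is.numeric(axial_pitch) || length(axial_pitch) != 1 || axial_pitch <= 0)
    stop_input("`axial_pitch` must be a single positive number (mm)")
  if (!is.numeric(lateral_pitch) || length(lateral_pitch) != 1 ||
      lateral_pitch <= 0)
    stop_input("`lateral_pitch` must be a single positive number (mm)")
  if (!is.numeric(incident_intensity) || length(incident_intensity) != 1 ||
      incident_intensity <= 0)
    stop_input("`incident_intensity` must be a single positive number")
  if (!is.numeric(backscatter_fraction) || length(backscatter_fraction) != 1 ||
      backscatter_fraction <= 0 || backscatter_fraction > 1)
    stop_input("`backscatter_fraction` must lie in (0, 1]")
  n_depth <- floor(depth_extent / axial_pitch)
  if (n_depth < 2)
    stop_input("`depth_extent` must cover at least 2 axial pixels")
  structure(
    list(axial_pitch = axial_pitch,
         lateral_pitch = lateral_pitch,
         depth_extent = depth_extent,
         incident_intensity = incident_intensity,
         backscatter_fraction = backscatter_fraction,
         n_depth = as.integer(n_depth)),
    class = "oct_geometry")
}

#' @export
print.oct_geometry <- function(x, ...) {
  cat(sprintf(
    "<oct_geometry> %d depths x %.4g mm axial pitch (%.3g mm deep), ",
    x$n_depth, x$axial_pitch, x$depth_extent))
  cat(sprintf("lateral pitch %.4g mm\n  I_inc = %.4g, backscatter fraction = %.3g\n",
              x$lateral_pitch, x$incident_intensity, x$backscatter_fraction))
  invisible(x)
}

as_value_matrix <- function(values, what) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`", what, "` must be a numeric matrix (depth x lateral) ",
               "or a vector (one A-line)")
  storage.mode(values) <- "double"
  values
}

#' Voxelwise attenuation map
#'
#' A grid of attenuation coefficients (mm^-1), depth down the rows and
#' lateral position across the columns, tied to an acquisition geometry.
#' A plain vector is treated as a single A-line.  `NA` entries are
#' permitted only when `allow_na = TRUE` (used by [estimate_map()] to mark
#' voxels excluded by the admissibility mask).
#'
#' @param values Numeric matrix (or vector) of non-negative attenuation
#'   coefficients in mm^-1; `nrow(values)` must equal `geometry$n_depth`.
#' @param geometry An [acquisition_geometry()].
#' @param allow_na Allow `NA` sentinels for undefined voxels.
#' @return An object of class `oct_profile` with fields `values` and
#'   `geometry`.
#' @export
attenuation_profile <- function(values, geometry, allow_na = FALSE) {
  stopifnot(inherits(geometry, "oct_geometry"))
  values <- as_value_matrix(values, "values")
  if (nrow(values) != geometry$n_depth)
    stop_input("profile has ", nrow(values), " depth rows but geometry ",
               "expects ", geometry$n_depth)
  if (!allow_na && anyNA(values))
    stop_input("attenuation values must not contain NA")
  if (any(values < 0, na.rm = TRUE))
    stop_input("attenuation coefficients must be non-negative")
  structure(list(values = values, geometry = geometry),
            class = "oct_profile")
}

#' @export
print.oct_profile <- function(x, ...) {
  v <- x$values
  cat(sprintf("<oct_profile> %d x %d attenuation map (mm^-1), range [%.4g, %.4g]\n",
              nrow(v), ncol(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' OCT intensity scan
#'
#' An intensity grid (depth down the rows, lateral across the columns)
#' with its acquisition geometry.  `is_realization = FALSE` marks a
#' speckle-free mean signal; `TRUE` marks one speckled draw, in which case
#' the generating `seed` is recorded.
#'
#' @param intensities Non-negative numeric matrix (or vector for a single
#'   A-line) matching `geometry$n_depth` rows.
#' @param geometry An [acquisition_geometry()].
#' @param is_realization Whether the field is a speckled realization.
#' @param seed Integer seed recorded for realizations (may be `NULL`).
#' @return An object of class `oct_scan`.
#' @seealso [mean_signal()], [speckle_sample()]
#' @export
scan_field <- function(intensities, geometry, is_realization = FALSE,
                       seed = NULL) {
  stopifnot(inherits(geometry, "oct_geometry"))
  intensities <- as_value_matrix(intensities, "intensities")
  if (nrow(intensities) != geometry$n_depth)
    stop_input("scan has ", nrow(intensities), " depth rows but geometry ",
               "expects ", geometry$n_depth)
  if (anyNA(intensities) || any(intensities < 0))
    stop_input("intensities must be non-negative and free of NA")
  structure(list(intensities = intensities, geometry = geometry,
                 is_realization = isTRUE(is_realization), seed = seed),
            class = "oct_scan")
}

#' @export
print.oct_scan <- function(x, ...) {
  cat(sprintf("<oct_scan> %d x %d %s, intensity range [%.4g, %.4g]\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$is_realization) "speckled realization" else "mean signal",
              min(x$intensities), max(x$intensities)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}
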