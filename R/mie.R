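#' Bead-suspension phantom specification
#'
#' Describes a monodisperse suspension of homogeneous spheres used as a
#' scattering tissue phantom.  Both the phase and the group refractive
#' index of the suspending medium are carried: the phase index sets the
#' wavelength inside the medium (hence the Mie size parameter), while the
#' index contrast that governs the backscattered OCT signal is taken
#' relative to the group index, following the OCT phantom literature.
#'
#' @param diameter Sphere diameter in micron (> 0).
#' @param n_particle Particle refractive index (>= 1).
#' @param n_medium_phase Phase refractive index of the medium (>= 1).
#' @param n_medium_group Group refractive index of the medium (>= 1);
#'   defaults to the phase index.
#' @param volume_fraction Particle volume fraction, in (0, 1).
#' @param wavelength_vacuum Vacuum wavelength in nm (> 0).
#' @return An object of class `oct_suspension`.
#' @examples
#' # silica beads in water at 1309 nm
#' s <- sphere_suspension(0.47, 1.425, 1.32, 1.34, 0.08, 1309)
#' mie_sigma_scat(s)  # about 1.9e-9 mm^2
#' @export
sphere_suspension <- function(diameter, n_particle, n_medium_phase,
                              n_medium_group = n_medium_phase,
                              volume_fraction, wavelength_vacuum) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop_input("`diameter` must be positive (micron)")
  if (!is.numeric(wavelength_vacuum) || wavelength_vacuum <= 0)
    stop_input("`wavelength_vacuum` must be positive (nm)")
  if (volume_fraction <= 0 || volume_fraction >= 1)
    stop_input("`volume_fraction` must lie in (0, 1)")
  if (any(c(n_particle, n_medium_phase, n_medium_group) < 1))
    stop_input("refractive indices must be >= 1")
  structure(
    list(diameter = diameter, n_particle = n_particle,
         n_medium_phase = n_medium_phase, n_medium_group = n_medium_group,
         volume_fraction = volume_fraction,
         wavelength_vacuum = wavelength_vacuum),
    class = "oct_suspension")
}

#' Mie efficiencies of a homogeneous sphere
#'
#' Full Mie series for scattering and extinction efficiencies, using the
#' logarithmic-derivative downward recurrence for the internal field and
#' upward recurrence for the Riccati-Bessel functions.  The series is
#' truncated at `x + 4 x^(1/3) + 2` terms.
#'
#' @param x Size parameter (2 pi a n_medium / lambda_vacuum).
#' @param m Relative refractive index (particle over medium); may be
#'   complex for absorbing particles.
#' @return A list with `q_sca`, `q_ext` and the number of series terms.
#' @export
mie_efficiencies <- function(x, m) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0)
    stop_input("`x` must be a single positive size parameter")
  m <- as.complex(m)
  nstop <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmx <- max(nstop, ceiling(Mod(m) * x)) + 16
  mx <- m * x
  D <- rep(0 + 0i, nmx)
  for (n in (nmx - 1):1) D[n] <- (n + 1) / mx - 1 / (D[n + 1] + (n + 1) / mx)
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  q_sca <- 0; q_ext <- 0
  for (n in seq_len(nstop)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    an <- ((D[n] / m + n / x) * psi - psi1) / ((D[n] / m + n / x) * xi - xi1)
    bn <- ((D[n] * m + n / x) * psi - psi1) / ((D[n] * m + n / x) * xi - xi1)
    q_sca <- q_sca + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    q_ext <- q_ext + (2 * n + 1) * Re(an + bn)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
    xi1 <- xi
  }
  list(q_sca = 2 / x^2 * q_sca, q_ext = 2 / x^2 * q_ext, n_terms = nstop)
}

#' Mie scattering cross-section of a suspended sphere
#'
#' Size parameter `x = pi * diameter * n_medium_phase / lambda_vacuum`;
#' relative index `m = n_particle / n_medium_group` (see
#' [sphere_suspension()] for why the group index enters the contrast).
#' Returns `Q_sca * pi * (diameter / 2)^2` in mm^2.
#'
#' @param s A [sphere_suspension()].
#' @return Scattering cross-section (mm^2).
#' @export
mie_sigma_scat <- function(s) {
  stopifnot(inherits(s, "oct_suspension"))
  d_mm <- s$diameter * 1e-3
  lambda_mm <- s$wavelength_vacuum * 1e-6
  x <- pi * d_mm * s$n_medium_phase / lambda_mm
  m <- s$n_particle / s$n_medium_group
  eff <- mie_efficiencies(x, m)
  eff$q_sca * pi * (d_mm / 2)^2
}

#' Number density of suspended spheres
#'
#' `volume_fraction / sphere_volume`, in mm^-3.
#'
#' @param s A [sphere_suspension()].
#' @return Number density (mm^-3).
#' @export
number_density <- function(s) {
  stopifnot(inherits(s, "oct_suspension"))
  r_mm <- s$diameter * 1e-3 / 2
  s$volume_fraction / ((4 / 3) * pi * r_mm^3)
}

#' Bulk attenuation coefficient of the suspension
#'
#' Independent-scattering (dilute) approximation: scattering
#' cross-section times number density.  No dependent-scattering
#' correction is applied.
#'
#' @param s A [sphere_suspension()].
#' @return Attenuation coefficient (mm^-1).
#' @export
bulk_attenuation <- function(s) {
  mie_sigma_scat(s) * number_density(s)
}

#' Voxel geometry for the prior width
#'
#' Records the three linear voxel dimensions and their product, the voxel
#' volume entering the prior width parameter.
#'
#' @param dims Numeric vector of the three linear dimensions (mm, > 0):
#'   axial pitch and the two lateral pitches.
#' @return An object of class `oct_voxel` with `voxel_volume` (mm^3) and
#'   `derivation` (the recorded dimensions).
#' @export
voxel_geometry <- function(dims) {
  if (length(dims) != 3 || any(dims <= 0))
    stop_input("`dims` must be three positive lengths (mm)")
  structure(list(voxel_volume = prod(dims), derivation = dims),
            class = "oct_voxel")
}

#' Prior width parameter from phantom physics
#'
#' `zeta = sigma_scat / voxel_volume`: the per-particle scattering
#' cross-section divided by the voxel volume.  The prior variance of the
#' attenuation coefficient is `zeta * layer_mean`.
#'
#' @param sigma_scat Scattering cross-section (mm^2, >= 0).
#' @param vox A [voxel_geometry()], or a single voxel volume in mm^3.
#' @return zeta (mm^-1).
#' @export
zeta_from_geometry <- function(sigma_scat, vox) {
  if (inherits(vox, "oct_voxel")) vox <- vox$voxel_volume
  if (!is.numeric(vox) || vox <= 0) stop_input("voxel volume must be positive")
  if (sigma_scat < 0) stop_input("`sigma_scat` must be non-negative")
  sigma_scat / vox
}

#' Derived optical properties of a phantom
#'
#' Flat summary of the suspension's derived quantities, suitable for JSON
#' export.
#'
#' @param s A [sphere_suspension()].
#' @param vox Optional [voxel_geometry()]; when given, `zeta_mm1` is
#'   included.
#' @return A named list: `sigma_scat_mm2`, `number_density_mm3`,
#'   `mu_bulk_mm1`, and optionally `zeta_mm1` and `voxel_volume_mm3`.
#' @export
phantom_report <- function(s, vox = NULL) {
  sigma <- mie_sigma_scat(s)
  out <- list(sigma_scat_mm2 = sigma,
              number_density_mm3 = number_density(s),
              mu_bulk_mm1 = sigma * number_density(s))
  if (!is.null(vox)) {
    out$voxel_volume_mm3 <- vox$voxel_volume
    out$zeta_mm1 <- zeta_from_geometry(sigma, vox)
  }
  out
}
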