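# octbayes

Bayesian voxelwise estimation of OCT attenuation coefficients under
speckle.

## What problem this solves

Optical coherence tomography (OCT) practitioners increasingly map the
attenuation coefficient µ_oct (mm⁻¹) — the exponential decay rate of the
mean signal with depth — voxel by voxel, using the depth-resolved (DR)
ratio estimator

    µ̂(N) = I_N / Σ_{i=N+1..M} 2·Δz·I_i .

Under fully developed speckle, however, each measured intensity I_N is an
exponential random variable around the speckle-free mean, and because the
denominator's coefficient of variation is small, the DR estimate itself
is (to leading order) **exponentially distributed around the true
coefficient**:

    P(µ̂ | µ_oct) = (1/µ_oct) · exp(−µ̂/µ_oct).

A single-voxel DR estimate therefore carries noise comparable to its own
value.  This package treats the recovery as Bayesian inference: the
exponential law above is the likelihood, a physics-based Gaussian prior
P(µ) with mean ⟨µ⟩ and variance ζ·⟨µ⟩ (ζ = σ_scat / voxel volume, from
Poisson scatterer-count statistics) encodes how much a homogeneous layer
can vary, and the posterior

    P(µ_oct | µ̂₁..µ̂_k) ∝ µ_oct⁻ᵏ · exp(−Σµ̂ᵢ/µ_oct) · P(µ_oct)

is tabulated and normalized numerically per voxel.  The recommended
single-number summary is the **posterior mean**; the posterior mode (MaP)
can sit on a narrow near-origin spike when µ̂ is small and the posterior
bimodal.  The package also ships the forward simulator (mean decay +
exponential speckle), the DR estimator with finite-depth tail completion
and admissibility masking, analytic hypoexponential denominator
statistics, Mie-theory phantom helpers, file I/O (float TIFF + JSON
sidecar, CSV), seeded end-to-end simulation workflows, and a small CLI.

Audience: OCT signal-processing researchers and phantom builders who
want voxelwise attenuation maps with honest uncertainty, and anyone who
needs a reproducible speckled-OCT simulator to benchmark attenuation
estimators.

## Worked example

```r
library(octbayes)

# reference geometry: 500 depths of 0.0068 mm (3.4 mm), 1000 A-lines
geom <- acquisition_geometry(axial_pitch = 0.0068, lateral_pitch = 0.022,
                             depth_extent = 3.4)
sim <- simulate_bscan(2.0, geom, n_lines = 1000, seed = 42)
dr  <- dr_estimate(sim$speckled, truncation_fraction = 0.3)
dr
#> <oct_dr_map> 500 x 1000 DR attenuation estimates (mm^-1), 350000 admissible
#>   truncation_fraction = 0.30, tail_mode = none
layer_mean(dr)
#> [1] 2.0598
```

The admissible DR estimates scatter exponentially around the true
2.00 mm⁻¹ (their pooled mean, 2.06, shows the estimator's known small
positive bias — see the vignette).  A single voxel whose DR estimate came
out at 0.35 mm⁻¹ is rehabilitated by the posterior:

```r
pr   <- prior_spec(layer_mean(dr), zeta = 5e-2)
post <- posterior(0.35, pr)
post
#> <oct_posterior> 4096-point grid on [0.000206, 5.619] mm^-1; k = 1 estimate(s)
#>   posterior mean 2.017 mm^-1, sd 0.3237 mm^-1
```

The posterior mean (2.02 mm⁻¹) sits near the layer mean with an honest
±0.32 mm⁻¹ spread, instead of the wild raw estimate 0.35.  Whole-map
version: `estimate_map(dr, pr)` (masked voxels become `NA`).  End-to-end
validation of the exponential law:

```r
rep <- run_homogeneous_validation(mu = 2, seed = 42)
c(rep$fitted_rate_mm1, rep$ks_p_value, range(rep$cv_analytic))
#> [1] 2.0598 0.4900 0.1166 0.1186
```

Phantom physics for a silica-beads-in-water suspension (0.47 µm beads,
volume fraction 0.08, 1309 nm):

```r
s <- sphere_suspension(0.47, 1.425, 1.32, 1.34, 0.08, 1309)
str(phantom_report(s, voxel_geometry(c(0.0068, 0.022, 0.022))))
#> List of 5
#>  $ sigma_scat_mm2    : num 1.91e-09
#>  $ number_density_mm3: num 1.47e+09
#>  $ mu_bulk_mm1       : num 2.81
#>  $ voxel_volume_mm3  : num 3.29e-06
#>  $ zeta_mm1          : num 0.00058
```

## Command line

A thin Rscript front-end lives at `inst/cli/octbayes.R`
(`system.file("cli", "octbayes.R", package = "octbayes")`):

```sh
octbayes.R simulate      --config run.yaml --out out/
octbayes.R dr            --config run.yaml --out out/
octbayes.R posterior     --config run.yaml --out out/
octbayes.R phantom-props --config phantom.yaml --out out/
octbayes.R baseline      --config run.yaml --window 10 --out out/
octbayes.R reproduce     --which validation|recovery|sweep --seed 1 --out out/
```

Configs are JSON or YAML (see `?read_run_config`); images are written as
32-bit TIFF plus a JSON sidecar carrying geometry, seed and scale.

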