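# subdrs

Monte Carlo forward modelling and look-up-table inversion of
**sub-diffusive diffuse reflectance** measured with compact multi-fiber
probes that use tilted, beveled optical fibers — aimed at estimating the
intrinsic optical properties of **bilayer tissue** (skin with a thin
lesion or epidermal layer over dermis).

At source–detector separations below about a transport mean free path,
reflectance depends not only on the absorption coefficient μa and the
reduced scattering coefficient μs′ but also on the similarity parameter

γ = (1 − g₂) / (1 − g₁),

where g₁ and g₂ are the first two Legendre moments of the scattering
phase function. For a bilayer medium the unknowns are seven:
(μs′₁, γ₁, μa₁) of the top layer, (μs′₂, γ₂, μa₂) of the deep layer, and
the interface depth z. `subdrs` implements the full simultaneous
estimation pipeline:

* **Photon transport** (`run_forward`): white Monte Carlo in layered
  slabs (oil film / finite top layer / deep layer) with a modified
  Henyey–Greenstein phase function whose γ is set exactly per layer,
  tilted/beveled fiber sources and NA-limited detectors, stochastic
  Fresnel boundaries, and per-layer partial path lengths stored per
  collected photon so that any absorption pair is applied afterwards by
  Beer–Lambert reweighting (`apply_absorption`).
* **Look-up tables** (`build_lut`, `lut_query`, `lut_read`/`lut_write`):
  gridded per-fiber-combination reflectance over the monolayer triplet or
  the seven bilayer axes; only the scattering × depth sub-grid needs
  simulations, the absorption axes come free from reweighting.
* **Inverse solver** (`grid_invert`, `cost_function`,
  `spectral_invert`, `landscape_slices`, `propagate_uncertainty`):
  exhaustive grid search on the mean weighted relative misfit, with
  deterministic tie-breaks, per-wavelength spectral estimation, 2-D cost
  landscapes with their sub-10% regions, and uncertainty propagation by
  re-inverting at (1 ± w_tot)·R.
* **Signal chain & calibration** (`correct_signal`, `fit_bias_and_slope`,
  `fit_temporal_nonlinearity`, `fit_intensity_nonlinearity`,
  `experimental_reflectance`, `joint_calibrate`): the raw CCD model
  S = I_DC + f_NL·(I_dark + I_amb + I)·t with Savitzky–Golay smoothing,
  and the joint estimation of one calibration coefficient α per fiber
  combination and one γ per reference phantom from integrating-sphere
  referenced measurements.
* **Synthetic studies** (`add_noise`, `noise_sweep`, `thickness_sweep`,
  `contrast_sweep`, `fiber_count_convergence`,
  `bilayer_recovery_study`): the desk-scale characterization experiments,
  reproducible bit-for-bit from a seed.

## A worked example

Build a small monolayer table for a three-detector probe, perturb the
reflectance of a known tissue-like node with 10% multiplicative noise,
and invert:

```r
library(subdrs)

probe <- radial_probe(c(0.1, 0.5, 0.9), tilts = 0)
probe
#> probe: 1 illumination + 3 detection fibers, 3 combinations (SDS 0.10-0.90 mm)

grid <- grid_spec(mus_p = c(1.0, 2.0, 3.0), gamma = c(1.2, 1.5, 1.8),
                  mua  = c(0, 0.2, 0.5, 1.0))
lut <- build_lut(grid, probe, n_photons = 1e5, seed = 7, oil_thickness = 0)
lut
#> reflectance LUT (monolayer): 36 nodes x 3 combinations, 9 MC runs, 100000 photons/node

truth <- c(mus_p = 2, gamma = 1.5, mua = 0.2)
meas <- add_noise(lut_reflectance(lut, truth), level = 0.10, seed = 42)
grid_invert(meas, lut)
#> grid estimate (cost 0.07663):
#> mus_p gamma   mua 
#>   2.0   1.5   0.2

pu <- propagate_uncertainty(meas, lut, w_tot = 0.10)
rbind(lower = pu$bounds_lo, estimate = pu$values, upper = pu$bounds_hi)
#>          mus_p gamma mua
#> lower        2   1.5 0.2
#> estimate     2   1.5 0.2
#> upper        2   1.5 0.2
```

The estimate lands back on the generating node (cost 0.077 ≈ the mean
absolute 10% noise), and scaling the data by ±10% does not move the
argmin off that node, so the propagated bounds collapse onto it. Only
grid values can ever be returned — queries snap to the nearest node and
the solver is a pure grid argmin, so recovered spectra are stepwise by
design.

The bilayer pipeline is identical in shape: `desk_bilayer_grid()` +
`build_probe()` (the default 16-fiber tilted probe) feed `build_lut`,
and `bilayer_recovery_study()` runs the noisy-recovery experiment over a
set of top-layer thicknesses.

A thin command-line wrapper ships in `inst/scripts/subdrs`
(`simulate`, `build-lut`, `invert`, `sweep` subcommands).

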