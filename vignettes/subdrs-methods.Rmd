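---
title: "Models and methods behind subdrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind subdrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subdrs)
```

# The problem

Spatially resolved diffuse reflectance spectroscopy (srDRS) infers the
intrinsic optical properties of tissue — the absorption coefficient
$\mu_a$, the reduced scattering coefficient $\mu_s'$ and, at
sub-millimetre source–detector separations (SDS), the sub-diffusive
similarity parameter $\gamma = (1-g_2)/(1-g_1)$ — from backscattered
light collected at several distances from the source. Skin is layered;
treating it as homogeneous yields coefficients that describe neither the
epidermis/lesion nor the dermis below. `subdrs` models the full
simultaneous bilayer problem: seven unknowns
$(\mu_{s,1}', \gamma_1, \mu_{a,1}, \mu_{s,2}', \gamma_2, \mu_{a,2}, z)$,
where $z$ is the depth of the interface, probed by a compact 16-fiber
probe whose fibers are tilted and beveled to diversify both the sampled
depths and the parts of the scattering phase function that the detected
photons interrogate.

The package contains the four ingredients of that pipeline, each usable on
its own: a layered-medium Monte Carlo forward model with tilted-fiber
sources and detectors, a look-up-table (LUT) machinery over the optical
property grids, an exhaustive grid inverse solver with uncertainty
propagation, and the spectrometer signal-processing / probe-calibration
chain. A synthetic-data layer reproduces the characterization studies
(noise, thickness, contrast, fiber count) at desk scale.

# Phase function and $\gamma$

Scattering is modelled with a modified Henyey–Greenstein (MHG) mixture

$$p(\mu) = \beta\, p_{HG}(\mu; g) + (1-\beta)\,\tfrac32 \mu^2 ,
\qquad \mu = \cos\theta,$$

whose Legendre moments are closed-form: $g_1 = \beta g$ and
$g_2 = \beta g^2 + (1-\beta)\,2/5$. This family was chosen because both
moments are controllable analytically — the LUT axes are $(\mu_s',
\gamma)$, so for every grid value of $\gamma$ the solver
`solve_phase_params()` inverts the moments exactly (a quadratic in
$\beta$) at the configured first moment. Any other two-moment family
could be swapped in by providing moments and an exact sampler.

Two consequences are worth knowing:

* $g_1$ is a fixed configuration constant (default 0.9, typical of
  forward-peaked tissue scattering), because the tables are indexed by
  $(\mu_s', \gamma)$ only; the scattering coefficient handed to the
  transport engine is $\mu_s = \mu_s'/(1-g_1)$.
* at $g_1 = 0.9$ the mixture attains $\gamma \in (0.6, 1.9]$: the upper
  end of the conventional tissue range, $\gamma = 2.0$, is not
  representable ($\beta$ would exceed 1), so all packaged grids stop at
  1.9. `gamma_range()` reports the attainable interval.

Sampling is exact: an HG deviate through the closed-form inverse CDF with
probability $\beta$, otherwise $\mu = (2u-1)^{1/3}$ for the $\cos^2$
component.

# Probe geometry, bevel and acceptance

The default probe (`default_probe_config()`) places eight illumination
and eight detection fibers (0.1 mm diameter, NA 0.22, core index 1.43) on
circles of 0.8 and 1.5 mm radius. Outer-circle fibers are tilted inward
by 30–60°, inner ones are perpendicular. The exact azimuths are a package
choice satisfying the published constraints — SDS from ≈0.1 mm up to
≈3 mm, tilt diversity, faces inside the probe tip — and any layout can be
supplied as YAML, so a microscopy-measured layout can replace the
default.

A fiber tilted by $\beta$ is beveled at $\beta$ so its face is flush with
the tip. Refraction at the beveled face changes the photon tilt by
$\gamma_B = \sin^{-1}(n_f \sin\beta / n_{ext}) - \beta$.
`effective_bevel_angle()` defaults to $n_{ext}=1$ (the textbook
exit-into-air formula, ≈15.7° added at $\beta = 30°$, undefined beyond
the TIR limit $n_f\sin\beta > 1$). The transport model, however, assumes
the probe face is in optical contact with the immersion-oil film
($n_{ext} = 1.45$) — there the bevel contribution nearly cancels and all
tilt angles are physical. This contact convention is what makes 45° and
60° fibers usable at all; with an air gap they would be beyond total
internal reflection.

Launch and acceptance are symmetric: positions uniform over the
elliptical beveled footprint, directions inside the in-medium acceptance
cone of half-angle $\sin^{-1}(\mathrm{NA}/n_{medium})$ around the
effective (tilt + bevel) axis. Acceptance is evaluated against the
photon's in-medium exit direction, before refraction out of the surface.

# White Monte Carlo transport

`run_forward()` propagates photons through analytic slabs: an optional
scattering-free oil film (default 0.05 mm, $n = 1.45$), a top layer of
thickness $z$, and a deep layer (semi-infinite by default). Free paths
are exponential at the layer's $\mu_s$; boundaries apply unpolarized
Fresnel coefficients stochastically (reflect with probability $R_F$, else
refract), so photon weights stay exactly 1 during transport. No
absorption is applied in flight: each collected photon's per-layer
partial path lengths $(\ell_1, \ell_2)$ are stored, and
`apply_absorption()` weights it by
$\exp(-\mu_{a,1}\ell_1 - \mu_{a,2}\ell_2)$ afterwards. One simulation per
scattering/depth node therefore serves the entire absorption grid — the
reason the 7-D table needs only $n_{\mu_s'}^2 n_\gamma^2 n_z$ runs.

An analog mode (`analog = TRUE`) samples absorption events during
transport instead; it exists purely as an independent cross-check of the
reweighting and the two agree within Monte Carlo error in the test suite.

Numerical choices:

* **Termination.** Photons are discarded beyond a total path of 200 mm or
  a lateral excursion of 15 mm (defaults). White MC cannot use roulette
  (weights must stay 1), so the cutoff truncates the long diffusive tail;
  the truncated count is reported in `counts`. For $\mu_a \gtrsim
  0.005\,\mathrm{mm^{-1}}$ the truncated weight is negligible
  ($e^{-0.005\cdot200} \approx 0.37$ times path-tail mass that is itself
  small); at $\mu_a = 0$ it is a documented bias bound, below the MC
  noise at the packaged photon budgets.
* **LUT-build cutoffs.** `build_lut()` scales the cutoffs with the
  transport mean free path of the least-scattering layer
  (path $\approx 25/\mu_{s,min}'$ mm, lateral $\approx 12/\mu_{s,min}'$ mm,
  both clamped to the transport defaults). Detected photons at SDS
  ≤ 3 mm overwhelmingly stay inside these envelopes; the truncated tail
  mainly affects the $\mu_a = 0$ slice, again below the per-combination
  MC noise at desk photon budgets. Passing explicit `max_path` /
  `max_lateral` restores any other convention.
* **Energy bookkeeping.** For a semi-infinite non-absorbing medium the
  return-path distribution is heavy-tailed (its mean diverges), so "all
  photons eventually exit" is unattainable under any finite cutoff. The
  conservation check therefore gives the deep layer a finite thickness
  (an index-matched open slab): reflected + transmitted weight equals the
  launched weight exactly, with zero truncation, which the acceptance
  suite asserts at $10^6$ launched photons. The semi-infinite default
  remains untouched for physics runs.
* **RNG.** A dedicated xoshiro256++ stream seeded per illumination fiber
  makes runs bit-reproducible and independent of R's global RNG state.

# Look-up tables and inversion

`build_lut()` fills a `reflectance_lut` over a `grid_spec`; nodes are
enumerated first-axis-fastest, queries snap to the nearest node (ties to
the lower value) with **no interpolation** — recovered spectra are
intentionally stepwise, mirroring the discrete grid search the method
uses. Optional multilinear interpolation was considered and rejected: the
published procedure is a pure grid argmin, and interpolation would blur
the self-consistency property the tests rely on.

The cost of a measurement against node $k$ is the mean weighted relative
difference

$$F_k = \frac{1}{n_c}\sum_{c}
\frac{|R^{sim}_{k,c} - R^{meas}_{c}|}{R^{sim}_{k,c}}\cdot\frac{1}{w_{tot,c}},$$

with unit weights by default (the convention of the geometry-landscape
studies, which predate calibration) and $1/w_{tot}$ weights available for
calibrated data. The simulated reflectance is the denominator, and
mean-absolute (not RMS) differences are used, consistent with the
absolute-value form of the calibration objective.

Empty Monte Carlo bins ($R^{sim}=0$ at a node, common at small photon
budgets) are resolved by support: a combination where both the node and
the measurement are zero carries no information and is dropped from that
node's mean, whereas a node predicting zero where signal was measured
cannot explain the data — its relative misfit is infinite — and is
excluded from the argmin, with the exclusion count reported. If that
strict rule disqualifies every node (possible when the measurement comes
from an independent sparse run whose support matches no node exactly),
the cost falls back to charging a unit relative misfit per conflicting
combination, with a message. On densely populated tables both rules
coincide with the plain formula. `grid_invert()` is an exhaustive argmin
with a deterministic
tie-break (smallest linear index, ties counted);
`propagate_uncertainty()` re-inverts at $(1 \pm w_{tot})R$ and reports the
per-parameter envelope; `landscape_slices()` exposes the 2-D cost maps
with their sub-10% contour region and its node-count area as the
compactness metric.

# Signal chain and calibration

The raw CCD signal model is

$$S(\lambda, t) = I_{DC} + f_t(t)\, f_i(x)\, x, \qquad
x = \big(I_{dark}(\lambda) + I_{amb}(\lambda) + I(\lambda)\big)\,t,$$

a zero-time bias, a combined dark-current/ambient slope (the two are
never measured separately, so they are estimated as one), a temporal
nonlinearity at long integration times, and an intensity nonlinearity
(the CCD under-responds at high counts) fitted as a third-degree
polynomial by least squares. The fitting chain is: Savitzky–Golay
smoothing (order 3, window 21 — exact on cubic spectra including the
edges, which are handled by truncated-window polynomial fits), shared
bias from per-wavelength linear fits on the low-$t$ regime (default: the
lowest third of integration times, configurable), per-wavelength
dark/ambient slopes with the bias fixed, temporal ratio
measured/linear-fit, and the pooled intensity-ratio cubic.

`correct_signal()` inverts the model in the order smoothing → bias →
temporal → **intensity → per-time conversion → dark/ambient**. The
intensity nonlinearity acts on total counts, so algebra forces its
inversion (monotone Newton solve of $f_i(x)x = y$) before dividing by $t$
and subtracting the slope; a correction order that defers it to the end
cannot reproduce the forward model exactly. The noiseless round trip is
exact to numerical precision.

Calibration compares the corrected object/integrating-sphere ratio
($\alpha R_{exp}$; all multiplicative system responses cancel) with
simulated reflectance on solid phantoms of known $(\mu_s', \mu_a)$ but
unknown $\gamma$. `joint_calibrate()` minimizes the summed weighted
absolute relative misfit over one scalar $\alpha_c$ per fiber combination
and one $\gamma_p$ per phantom (on the LUT's $\gamma$ grid). Because the
optimal $\alpha_c$ for fixed $\gamma$ is an exact weighted median,
$\gamma$ is profiled out by exact enumeration of the grid combinations
(up to a configurable limit, with alternating minimization as a
fallback). Enumeration was adopted after observing that plain alternation
can stall in local minima of this discrete landscape; with it, noiseless
synthetic phantoms are recovered exactly. Zero uncertainties receive a
floor at the smallest positive value, with a message.

# The synthetic-data layer, and what desk scale does and does not show

`add_noise()` implements multiplicative white Gaussian noise
$R \to R(1 + \sigma\varepsilon)$ — the natural reading of "percent noise"
on reflectance — with negative values clipped at zero and counted.
Characterization studies (`noise_sweep()`, `thickness_sweep()`,
`contrast_sweep()`, `fiber_count_convergence()`,
`bilayer_recovery_study()`) default to 20 trials per condition. Each
sweep can draw its truths in two modes, and every result labels which:
`"lut"` takes the measurement from the LUT node itself (solver
self-consistency — isolates the response to added noise from Monte Carlo
sparseness) and `"mc"` from a fresh off-LUT run at the snapped truth
(realism — includes independent MC noise and support mismatch). The
packaged studies use self-consistency mode for the noise-response and
thickness questions, and realism mode for the contrast study, whose
subject — whether the interface depth is physically identifiable at low
inter-layer contrast — would be masked by the exact support fingerprint
of self-consistency data. Contrast is defined as the common fractional
increase of the three deep-layer properties over their axis ranges,
starting from the smallest simulated values; the interface depth stays
in the report even at zero contrast, where it is unidentifiable and its
error measures the confusion baseline.

The packaged problem sizes are the package's compute envelope, chosen for
a single CPU:

* bilayer grid: 3 × 3 scattering values per layer × 8 absorption values
  per layer × 5 interface depths (0.2–1.0 mm) — 405 Monte Carlo runs at
  $10^5$ photons each (≈ 5–10 min);
* monolayer study grids: 3–4 values per axis, $10^5$–$2\times10^5$
  photons per node;
* study probes for the source–detector-geometry experiments use one
  central source with fanned detectors, NA 0.4 and 0.1–0.2 mm diameters —
  the reference values of the diameter/NA study, which found that
  diameter and NA change collected counts but not path-length
  distributions, so the physics probed is unchanged while statistics
  improve.

What this scale demonstrates: the correctness of the machinery
(reweighting, grids, argmin, tie-breaks, calibration algebra), the
qualitative trends (noise linearity, fiber-count convergence, landscape
compaction, thickness and contrast behaviour), and exact
self-consistency. What it does not demonstrate: physically converged
per-combination reflectance for 0.1 mm / NA 0.22 fibers — at $10^5$
photons per node a combination collects of order 1–10 photons, versus
the $10^8$ photons per node the full-scale study used on a GPU cluster.
Absolute reflectance values from desk-scale tables should be treated as
statistically sparse; the recovery studies are therefore
self-consistency twins, not re-measurements of the published phantom
errors.

# Known limitations

* Nearest-node semantics make all estimates grid-valued; discretization
  error is bounded by half the axis spacing and dominates at desk grid
  sizes (the published full grid uses 10–20 values per axis and reports
  exactly this as its own main limitation).
* The $\gamma$ axis cannot reach 2.0 with the MHG family at $g_1 = 0.9$.
* The oil film is a uniform slab in optical contact with the probe; no
  air gaps, no meniscus, no polarization, no time-of-flight.
* Fiber positions are ideal config values; the microscopy-based
  extraction of as-built positions is out of scope (positions are inputs).
* Sequential (two-step) bilayer estimation is intentionally not
  implemented; the simultaneous seven-parameter inversion is the point.
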