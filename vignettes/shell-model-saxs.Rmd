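---
title: "Shell-model SAXS of protein-encapsulating liposomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-model SAXS of protein-encapsulating liposomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `luvsaxs`, the numerical
choices behind it, and what the synthetic-data tests do and do not
demonstrate about real measurements.

## 1. The physical picture

A large unilamellar vesicle (LUV) in solution scatters X-rays according to
the excess electron (scattering) density of its parts relative to the
buffer. For a ganglioside/cholesterol/phosphatidylcholine vesicle the wall
is strongly structured: hydrated and phosphocholine headgroup layers sit
*above* water density (positive contrast), the hydrocarbon chain core sits
*below* it (negative contrast), and the oligosaccharide chains protruding
from the outer leaflet form a weak positive layer. The aqueous core — the
water pool — has zero contrast when the vesicle is empty.

Encapsulated protein changes exactly one thing in this description: it
raises the pool contrast from zero to `phi * (rho_p - rho_w)`, where `phi`
is the protein volume fraction of the pool, `rho_w = 9.38` and
`rho_p ~ 11.7--12.0` (units of 1e10 cm^-2) are the water and protein
scattering densities for X-rays. Full occupancy with `rho_p = 12.0` gives
a relative pool contrast of 2.62 — the "2.6" endpoint used throughout the
package. Because the pool volume is large compared to the wall volume, even
a few percent occupancy shifts the intensity-weighted structure noticeably:
the radius of gyration drops steeply at *low* occupancy, which is what
makes the Rg decrement a usable assay for encapsulation.

## 2. Forward model

### Amplitude and intensity

For spherical concentric regions the amplitude is assembled in the
annular-region convention: each region contributes its own contrast times
the difference of consecutive solid-sphere amplitudes
(`shell_amplitude()`). The algebraically identical boundary-difference
form (density steps at boundaries) is implemented independently in the test
suite and used as an oracle, alongside brute-force radial quadrature of the
piecewise-constant density. Ellipsoidal regions are handled in
`intensity_monodisperse()` by Gauss-Legendre quadrature of the orientation
average with effective radii `r_i * sqrt(1 + x^2 (nu_i^2 - 1))`; the
boundary *volumes* stay at the true ellipsoid values `nu_i * (4/3) pi
r_i^3`, so the forward intensity `I(0)` equals the squared excess
scattering mass regardless of the axial ratios.

### Polydispersity

`intensity_polydisperse()` integrates the single-particle intensity over a
truncated-Gaussian *number* distribution of the outer radius (mean 400 Å,
30 % standard deviation for the canonical fixture, truncated at
`r_min = 100` Å and renormalized). No extra volume weighting is applied:
the `V^2` weighting is already inside the single-particle intensity. Two
conventions relate the template profile to a particle of radius `R`:

* `fixed_thickness` (default): wall thicknesses are fixed, the pool radius
  absorbs the size change. This is the physically motivated choice — a
  bilayer's thickness does not scale with vesicle size, and the smallest
  possible vesicle is set by its wall. It also fixes `r_min` naturally:
  `r_min` must exceed the total wall thickness (60 Å for the fixture; we
  use 100 Å so the smallest vesicles retain a 40 Å pool).
* `proportional`: all radii scale; provided for sensitivity checks.

The mean radius of 400 Å is interpreted as the mean *outer* radius; the
alternative (pool-radius) reading is available by constructing the profile
accordingly.

### Quadrature orders

The radial integral uses Gauss-Legendre with 201 nodes on
`[r_min, mean + 6 sigma]`, validated against a 2000-node Riemann sum to
1e-4 relative. This order is not arbitrary: the integrand oscillates in `R`
with period `~pi/q`, so the node spacing must stay below roughly a third of
that at the largest `q` of interest. Under-resolving this integral is
dangerous rather than merely inaccurate — during development an
under-resolved fit objective developed spurious optima that attracted the
optimizer. The orientation average uses 64 nodes on `x in [0, 1]`,
validated against a 1e5-point trapezoid to 1e-6 relative.

## 3. Real-space and Guinier analyses

### p(r)

`distance_distribution()` evaluates `p(r) = (r / 2 pi^2) int q I(q)
sin(qr) dq` by trapezoidal quadrature on the curve's own grid. Two
truncation corrections are applied by default, both optional:

* a cosine taper over the last decade of q, suppressing high-frequency
  truncation ripples that would otherwise contaminate the sub-bilayer
  region where the empty/filled comparison is made;
* a low-q Guinier extension: the integral formally starts at q = 0, but
  measured (and simulated) curves start at some `q_min`. The lowest points
  of the curve are fitted with `I_0 exp(-q^2 Rg^2 / 3)` and the integrand
  is extended to zero on a fine auxiliary grid. Without this, curves whose
  first point is not deep inside the Guinier regime acquire a slowly
  oscillating artifact that grows with `r` and can displace the global
  maximum entirely. This is the same role the extrapolation step plays in
  standard indirect-transform practice; the direct transform is kept per
  the source analysis, only the integral's missing head is completed.

The peak position is refined by a three-point parabola around the discrete
maximum. `ripple_extent()` reports the largest sub-100 Å abscissa at which
p(r) changes sign, requiring at least two sign changes between lobes
exceeding 0.5 % of `max |p|` (so solid-sphere truncation wiggles do not
count as bilayer structure).

### Guinier fits

`guinier_fit()` regresses `ln I` on `q^2` over the largest low-q window
with `q Rg <= 1.0`, iterating the window to self-consistency and weighting
by `(I/sigma)^2` when uncertainties are present. The bound of 1.0 (rather
than the classic 1.3) suits vesicle-sized particles, whose curvature
departs from the Guinier law early. A caveat the tests quantify: even at
`q Rg <= 1` the fitted slope carries a systematic bias of about +1 % in Rg
for a solid sphere, because the highest-q points of the window dominate the
regression leverage. Consistency checks against the closed-form shell Rg
(`analytic_rg()`, `Rg^2 = (3/5) sum Δρ (r_i^5 - r_{i-1}^5) / sum Δρ (r_i^3
- r_{i-1}^3)`) are therefore asserted at 2 %, and empty/filled comparisons
always use the *same* estimator on both curves, so the bias cancels where
it matters.

## 4. Shell-model fitting

`fit_shell_model()` minimizes squared log-intensity residuals over
`q <= 0.2` (above which the spherical idealization of a real bilayer stops
holding), weighted by `(I/sigma)^2` when available, with box bounds on the
free parameters. Design points:

* **Log residuals** because the curves span ~4 intensity decades and both
  the low-q shoulder and the mid-q bilayer hump must be matched.
* **Free global scale**, profiled analytically at every objective
  evaluation, since relative-intensity data carry no absolute scale. This
  creates an exact gauge freedom when *every* contrast is free (contrasts
  `* alpha`, scale `/ alpha^2`); recovery tests pin one wall contrast.
* **Optimizer**: L-BFGS-B followed by a Nelder-Mead polish (Brent in one
  dimension). The log-residual surface has long, nearly flat, gently curved
  valleys where quasi-Newton steps stall; the simplex descends them. A
  deterministic restart schedule (fixed internal seed, jittered starts
  within the box) re-launches the search while the best objective exceeds a
  noise-floor tolerance derived from the data's uncertainties. Everything
  is reproducible from the inputs; there is no global search, matching the
  local-refinement character of the original procedure.
* **Score**: the reliability factor `R = sum |I_obs - I_model| / sum
  I_obs`, reported on the fit range against the scaled model.

Recovery behavior worth knowing: with the canonical fixture and 1 %
counting noise, the thin (6 Å) hydration layer's contrast is poorly
determined (tens of percent), while headgroup and core contrasts recover to
a few percent — thin, weakly contrasted layers are simply close to the
information limit of a 1-D curve. The 5 %-median recovery property is
asserted over random well-conditioned profiles, which is what it claims.

## 5. Occlusion analysis and the efficiency relation

`rg_contrast_sweep()` substitutes each pool contrast into region 1,
recomputes the polydisperse curve, and records Guinier Rg and p(r) peak;
both decrease monotonically on the canonical fixture, steepest at low
contrast. `build_efficiency_relation()` composes

    concentration (% w/v) -> phi = c * v_bar / 100
                          -> contrast = phi * (rho_p - rho_w)
                          -> model Rg -> decrement (Rg_0 - Rg_c) / Rg_0

on a concentration grid, and `estimate_encapsulated_concentration()`
inverts it at a measured decrement by monotone interpolation *in contrast*,
converting back to concentration only at the end. Because the model Rg
depends on the constants only through the contrast, the sensitivity band
over `rho_p in [11.7, 12.0]` and `v_bar in [0.70, 0.75]` is exact, not
re-simulated. Defaults: `v_bar = 0.73` cm^3/g (typical globular protein)
and `rho_p = 11.85` (midpoint of the X-ray range); the source analysis does
not state its choices, so the ~5.5 % w/v reproduction carries these
assumptions, which is why the estimate is always reported with its band.
Encapsulated concentration is defined per water-pool volume (g protein per
100 mL of pool).

## 6. The canonical fixture and what the generator emulates

No raw curves of the original measurements are available, so the package
ships a synthetic stand-in: a five-region wall (hydration 6 Å at +0.80,
inner headgroup 9 Å at +2.30, hydrocarbon core 24 Å at −2.28, outer
headgroup 9 Å at +2.30, oligosaccharide layer 12 Å at +1.35) around a
variable-contrast pool, with the 400 Å / 30 % truncated-Gaussian size
distribution. The wall contrast *profile shape* (sign pattern and relative
magnitudes) follows the published picture of such vesicles; the absolute
values are calibration constants, chosen once (script:
`scripts/calibrate_fixture.R`) so the *empty* model reproduces the
published observables — Guinier Rg in the 500–650 Å bracket, p(r) maximum
near 700 Å moving to near 500 Å at pool contrast 2.6, bilayer ripple out to
~55 Å, and an Rg decrement of ~0.14 near pool contrast 0.1 so that the
measured 587 → 501–509 Å decrement inverts to the several-percent w/v
scale. The effective knob is the sugar-layer contrast, which sets the net
wall excess (small and positive); everything else was left at its initial,
chemically sensible sketch value.

`synth_curve()` adds heteroscedastic Gaussian noise `sigma_I = floor * I +
scale * sqrt(I)` (relative floor plus counting statistics), reproducible
per seed; the default 1 % floor emulates the visual noise level of good
synchrotron data. `synth_mixture()` adds a Guinier-sphere term for free
(un-entrapped) protein, emulating the before-spin-filtration scenario.

What passing tests on these fixtures show: that the *methods* — transform,
Guinier, fit, sweep, inversion — are mutually consistent, correctly
normalized against independent oracles, and stable under the modeled noise.
What they do not show: that a real vesicle preparation matches the fixture.
Real data add instrumental smearing, background subtraction residuals,
inter-vesicle interference at finite concentration, possible multilamellar
contamination, and protein adsorbed to the wall rather than dissolved in
the pool — all outside this model (deliberately: the occlusion picture
treats encapsulation purely as a uniform pool-contrast change).

## 7. Problem sizes and runtime choices

Default grids are chosen so every analysis runs in seconds on one core: 600
q-points (log below 0.003 Å⁻¹, uniform above, so the transform does not
alias out to r = 2000 Å), 201 radial nodes, 27-point contrast sweeps, 1 Å
real-space steps where peak positions are read off. The test suite's
simulation studies (50-profile Guinier consistency, 20-seed noisy recovery)
use the same sizes and complete in a few minutes total.

## 8. Known limitations

* No instrumental resolution (smearing) correction and no absolute-
  intensity calibration; all intensities are relative.
* The direct transform requires curves reaching `q_max * D_max ≳ 10`;
  heavily truncated curves need the taper and low-q extension, and peak
  positions then inherit a few-percent dependence on the extension.
* The Guinier estimator at `q Rg <= 1` has a ~1 % positive bias that
  cancels in empty/filled ratios but not in absolute Rg values.
* The fit is local; a grossly wrong starting profile can converge to a
  wrong basin despite the restart schedule. Start from a physically
  motivated wall model.
* Encapsulation estimates assume the protein is uniformly dissolved in the
  pool; adsorption to the bilayer would bias the inferred concentration
  upward.
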