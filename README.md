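# luvsaxs

Shell-model analysis of solution small-angle X-ray scattering (SAXS) from
large unilamellar vesicles (LUVs), aimed at the question: **how much protein
did a liposome actually encapsulate?** Protein taken up into the aqueous
core (the "water pool") raises the pool's average excess scattering density
(contrast) above that of the surrounding buffer. That single change
reshapes the whole scattering curve — the low-q shoulder flattens, the
distance-distribution peak moves inward, the sub-bilayer ripple is damped,
and the apparent radius of gyration drops sharply. `luvsaxs` forward-models
these effects and inverts the measured R<sub>g</sub> decrement into an
encapsulated protein concentration.

The package is aimed at structural biophysicists and liposome/drug-delivery
researchers who have 1-D SAXS curves of empty and protein-loaded vesicles
and want a quantitative, reproducible encapsulation estimate.

## The model

A vesicle is described as `n` concentric regions (region 1 = water pool),
region `i` having outer radius `r_i`, axial ratio `nu_i` and contrast
`Δρ̄_i` (relative units; 1 unit = 10¹⁰ cm⁻²). For spherical regions the
scattering amplitude is

    A(q) = Σ_i Δρ̄_i [ V(r_i) Φ(q r_i) − V(r_{i−1}) Φ(q r_{i−1}) ],
    V(r) = (4/3) π r³,   Φ(x) = 3 j₁(x) / x,

with `j₁` the first-order spherical Bessel function; ellipsoidal regions
are handled by a Gauss–Legendre orientation average. Polydispersity enters
as a truncated-Gaussian number distribution `D(R)` of the outer radius,

    I(q) = ∫_{R_min} D(R) I_s(q, R) dR,

with the wall thicknesses held fixed while the pool radius varies. On top
of the forward model the package provides:

- `distance_distribution()` — p(r) = (r/2π²) ∫ q I(q) sin(qr) dq by direct
  Fourier transform, with a cosine taper and a low-q Guinier extension of
  the truncated integral;
- `guinier_fit()` — iterated, uncertainty-weighted Guinier regression,
  `Rg = sqrt(−3 · slope)`;
- `fit_shell_model()` — bounded least squares on log-intensities, scored by
  the reliability factor `R = Σ|I_obs − I_model| / Σ I_obs`;
- `rg_contrast_sweep()`, `build_efficiency_relation()`,
  `estimate_encapsulated_concentration()` — the occlusion analysis:
  concentration → pool volume fraction → pool contrast → model Rg, then the
  monotone inverse at a measured decrement;
- `canonical_fixture()`, `synth_curve()`, `synth_mixture()` — a calibrated
  five-shell ganglioside/cholesterol/egg-PC vesicle fixture and synthetic
  noisy curves, so the whole pipeline runs without measured data.

## Worked example

```r
library(luvsaxs)

fx <- canonical_fixture()      # empty LUV: pool contrast 0
fx$profile
#> shell_profile: 6 regions, outer radius 400.0 A
#>   r_outer thickness contrast axial_ratio
#> 1     340       340     0.00           1
#> 2     346         6     0.80           1
#> 3     355         9     2.30           1
#> 4     379        24    -2.28           1
#> 5     388         9     2.30           1
#> 6     400        12     1.35           1

curve <- model_curve(fx$profile, fx$dist)
guinier_fit(curve)
#> Guinier fit: Rg = 542.0 +/- 0.1 A, I(0) = 4.081e+14, 119 points,
#>   q in [0.0003, 0.0018] (q.Rg <= 0.99)

distance_distribution(curve)
#> distance_distribution: r in [0, 2000] A, peak at 740.2 A, ripple extent 63.7 A

rel <- build_efficiency_relation(fx$profile, fx$dist,
                                 c_grid = seq(0, 12, by = 0.5))
est <- estimate_encapsulated_concentration(rg_empty = 587, rg_filled = 506,
                                           relation = rel)
str(est)
#> List of 4
#>  $ concentration: num 5.77
#>  $ band         : num [1:2] 5.3 6.41
#>  $ decrement    : num 0.138
#>  $ contrast     : num 0.104
```

Reading: the empty model vesicle has a Guinier radius of 542 Å and a p(r)
peaking at 740 Å with a bilayer ripple out to ~64 Å. Feeding measured radii
of gyration of 587 Å (empty) and 506 Å (filled) through the fixture's
efficiency relation, the 13.8 % R<sub>g</sub> decrement corresponds to a
pool contrast of 0.10 relative units, i.e. an encapsulated protein
concentration of ≈ 5.8 % w/v (5.3–6.4 % over the plausible ranges of the
protein scattering density and partial specific volume).

A command-line interface wrapping the same functions ships in
`inst/cli/luvsaxs.R` (subcommands `simulate`, `synth`, `pr`, `guinier`,
`fit`, `occlusion`, `run`), and `run_pipeline()` executes the whole chain
from one YAML config.

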