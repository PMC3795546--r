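# Synthetic inputs: the canonical ganglioside/cholesterol/egg-PC LUV
# fixture, noisy synthetic curves, and LUV + free-protein mixtures.

# Frozen fixture constants (see scripts/calibrate_fixture.R for how they
# were obtained). Thicknesses inside-out: hydration shell, inner headgroup,
# hydrocarbon core, outer headgroup, protruding oligosaccharide layer.
.fixture_constants <- list(
  thicknesses = c(hydration = 6, inner_head = 9, core = 24,
                  outer_head = 9, sugar = 12),
  contrasts = c(hydration = 0.80, inner_head = 2.30, core = -2.28,
                outer_head = 2.30, sugar = 1.35),
  mean_radius = 400,
  sigma_percent = 30,
  r_min = 100
)

#' Canonical LUV bilayer fixture
#'
#' A five-region wall profile for a ganglioside/cholesterol/egg-PC large
#' unilamellar vesicle, wrapped around a water pool of variable contrast.
#' From the inside out: a high-density hydration shell (weak positive
#' contrast), the inner phosphocholine headgroup layer (high positive), the
#' hydrocarbon core (negative), the outer headgroup layer (high positive)
#' and the protruding oligosaccharide layer of the ganglioside headgroups
#' (low positive). The wall contrasts are frozen calibration constants
#' chosen so that the empty-vesicle model reproduces the characteristic
#' observables of such liposomes: a p(r) ripple extending to about 55
#' \eqn{\mathrm{\AA}}, a low-q shoulder near \eqn{q \approx 0.01}
#' \eqn{\mathrm{\AA}^{-1}} with a broad rounded peak over 0.04--0.2
#' \eqn{\mathrm{\AA}^{-1}}, and a Guinier radius in the 500--650
#' \eqn{\mathrm{\AA}} range for the default size distribution (mean outer
#' radius 400 \eqn{\mathrm{\AA}}, 30\% standard deviation, truncated at 100
#' \eqn{\mathrm{\AA}}). The calibration script is shipped in
#' `scripts/calibrate_fixture.R`.
#'
#' @param core_contrast water-pool contrast (relative units; 0 = empty
#'   vesicle, about 2.6 = fully protein-occupied).
#' @param mean_radius,sigma_percent,r_min size-distribution parameters;
#'   defaults are the fixture's study conditions.
#' @return list with elements `profile` (a [shell_profile()]) and `dist`
#'   (a [size_distribution()]), class `canonical_fixture`.
#' @export
canonical_fixture <- function(core_contrast = 0,
                              mean_radius = .fixture_constants$mean_radius,
                              sigma_percent = .fixture_constants$sigma_percent,
                              r_min = .fixture_constants$r_min) {
  fc <- .fixture_constants
  wall <- sum(fc$thicknesses)
  profile <- vesicle_profile(core_radius = mean_radius - wall,
                             thicknesses = fc$thicknesses,
                             contrasts = fc$contrasts,
                             core_contrast = core_contrast)
  dist <- size_distribution(mean_radius, sigma_percent = sigma_percent,
                            r_min = r_min)
  structure(list(profile = profile, dist = dist), class = "canonical_fixture")
}

#' @export
print.canonical_fixture <- function(x, ...) {
  cat("canonical LUV fixture\n")
  print(x$profile); print(x$dist)
  invisible(x)
}

#' Heteroscedastic counting-statistics noise model
#'
#' Per-point uncertainty \eqn{\sigma_I = \mathrm{floor} \cdot I +
#' \mathrm{scale} \cdot \sqrt{I}}: a relative noise floor plus a
#' counting-statistics term.
#'
#' @param floor relative noise floor (fraction of I).
#' @param scale counting-statistics scale (intensity units^1/2).
#' @param seed integer seed fixing the noise stream.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(floor = 0.01, scale = 0, seed = 1) {
  if (floor < 0 || scale < 0)
    abort_luvsaxs("noise components must be nonnegative", "invalid_configuration")
  structure(list(floor = floor, scale = scale, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthesize a noisy scattering curve from a shell model
#'
#' Computes the polydisperse model intensity and perturbs it with Gaussian
#' noise of standard deviation \eqn{\sigma_I = \mathrm{floor}\cdot I +
#' \mathrm{scale}\cdot\sqrt{I}}; the `sigma` column of the returned curve
#' holds \eqn{\sigma_I}. Reproducible: the same seed yields the same curve.
#'
#' @param profile a [shell_profile()].
#' @param dist a [size_distribution()].
#' @param noise a [noise_model()]; `NULL` returns the exact model curve.
#' @param q q grid (default [default_q_grid()]).
#' @param ... passed to [intensity_polydisperse()].
#' @return a [scattering_curve()] with `sigma` populated when noise is
#'   applied.
#' @export
synth_curve <- function(profile, dist, noise = noise_model(),
                        q = default_q_grid(), ...) {
  I <- intensity_polydisperse(profile, dist, q, ...)
  if (is.null(noise)) return(scattering_curve(q, I))
  if (!inherits(noise, "noise_model"))
    abort_luvsaxs("noise must be a noise_model or NULL", "invalid_configuration")
  sigma <- noise$floor * I + noise$scale * sqrt(pmax(I, 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  I_noisy <- I + stats::rnorm(length(I), 0, sigma)
  scattering_curve(q, I_noisy, sigma = sigma,
                   metadata = list(noise_floor = noise$floor,
                                   noise_scale = noise$scale,
                                   seed = noise$seed))
}

#' Mix a vesicle curve with free (un-entrapped) protein scattering
#'
#' Emulates a liposome solution before spin-filtration: the incoherent sum
#' of the vesicle curve and a dilute globular-protein term modeled as a
#' sphere form factor of equal radius of gyration
#' (\eqn{R = \sqrt{5/3}\,R_g}). The protein forward intensity is set as a
#' fraction of the vesicle forward intensity (taken at the curve's lowest
#' q).
#'
#' @param luv_curve a [scattering_curve()] of the vesicle alone.
#' @param protein_rg protein radius of gyration (\eqn{\mathrm{\AA}};
#'   default 16, globular-monomer scale).
#' @param protein_i0_fraction protein forward intensity as a fraction of the
#'   vesicle forward intensity.
#' @param noise optional [noise_model()] applied to the mixture.
#' @return a [scattering_curve()].
#' @export
synth_mixture <- function(luv_curve, protein_rg = 16,
                          protein_i0_fraction = 0, noise = NULL) {
  if (!inherits(luv_curve, "scattering_curve"))
    abort_luvsaxs("luv_curve must be a scattering_curve", "invalid_curve")
  if (protein_rg <= 0)
    abort_luvsaxs("protein_rg must be positive", "domain_error")
  if (protein_i0_fraction < 0)
    abort_luvsaxs("protein_i0_fraction must be nonnegative", "domain_error")
  q <- luv_curve$q
  R <- sqrt(5 / 3) * protein_rg
  I_p <- protein_i0_fraction * luv_curve$I[1] * sphere_form_amplitude(q * R)^2
  I_mix <- luv_curve$I + I_p
  if (is.null(noise)) return(scattering_curve(q, I_mix))
  sigma <- noise$floor * I_mix + noise$scale * sqrt(pmax(I_mix, 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  scattering_curve(q, I_mix + stats::rnorm(length(q), 0, sigma), sigma = sigma)
}
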