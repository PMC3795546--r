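# Multi-shell vesicle form factor: orientationally averaged intensity of a
# concentric-shell (optionally ellipsoidal) particle, integrated over a
# truncated-Gaussian size distribution.

#' Construct a multi-shell scattering-density profile
#'
#' A vesicle (or any concentric particle) is described as `n` nested regions.
#' Region 1 is the innermost solid region -- for a liposome, the water pool --
#' extending from the center to `radii[1]`; region `i` extends from
#' `radii[i-1]` to `radii[i]`. Each region carries an excess scattering
#' density (contrast) relative to the solvent, in relative units of
#' \eqn{10^{10}\,\mathrm{cm}^{-2}}, and an axial ratio for ellipsoidal
#' deformation (1 = spherical).
#'
#' @param radii outer radii (semi-axes) of the regions, strictly increasing,
#'   in \eqn{\mathrm{\AA}}.
#' @param contrasts excess scattering densities of the regions (relative
#'   units; 1 unit = \eqn{10^{10}\,\mathrm{cm}^{-2}}).
#' @param axial_ratios axial ratios \eqn{\nu_i > 0}; recycled to the number
#'   of regions. All 1 gives a spherical particle.
#' @return an object of class `shell_profile`.
#' @export
shell_profile <- function(radii, contrasts, axial_ratios = 1) {
  radii <- as.numeric(radii)
  contrasts <- as.numeric(contrasts)
  n <- length(radii)
  axial_ratios <- rep_len(as.numeric(axial_ratios), n)
  if (n < 1L) abort_luvsaxs("profile needs at least one region", "invalid_profile")
  if (length(contrasts) != n)
    abort_luvsaxs("radii and contrasts must have equal length", "invalid_profile")
  if (any(!is.finite(radii)) || any(radii <= 0) || any(diff(radii) <= 0))
    abort_luvsaxs("radii must be positive, finite and strictly increasing",
                  "invalid_profile")
  if (any(!is.finite(contrasts)))
    abort_luvsaxs("contrasts must be finite", "invalid_profile")
  if (any(!is.finite(axial_ratios)) || any(axial_ratios <= 0))
    abort_luvsaxs("axial ratios must be positive and finite", "invalid_profile")
  structure(list(radii = radii, contrasts = contrasts,
                 axial_ratios = axial_ratios),
            class = "shell_profile")
}

#' Construct a vesicle profile from a core radius and wall thicknesses
#'
#' Convenience constructor for liposome-like particles: an aqueous core of
#' radius `core_radius` and contrast `core_contrast` (0 for pure water),
#' wrapped in wall regions of given thicknesses (hydration layer, headgroups,
#' hydrocarbon core, sugar layer, ...), listed from the inside out.
#'
#' @param core_radius radius of the water pool (\eqn{\mathrm{\AA}}).
#' @param thicknesses wall-region thicknesses, inside out (\eqn{\mathrm{\AA}}).
#' @param contrasts wall-region contrasts (relative units), same length.
#' @param core_contrast contrast of the water pool (0 = no encapsulated
#'   material).
#' @param axial_ratios axial ratios, recycled over all regions incl. the core.
#' @return a `shell_profile` with `length(thicknesses) + 1` regions.
#' @export
vesicle_profile <- function(core_radius, thicknesses, contrasts,
                            core_contrast = 0, axial_ratios = 1) {
  if (!is_number(core_radius) || core_radius <= 0)
    abort_luvsaxs("core_radius must be a positive number", "invalid_profile")
  if (length(thicknesses) != length(contrasts))
    abort_luvsaxs("thicknesses and contrasts must have equal length",
                  "invalid_profile")
  shell_profile(radii = core_radius + cumsum(c(0, thicknesses)),
                contrasts = c(core_contrast, contrasts),
                axial_ratios = axial_ratios)
}

#' @export
print.shell_profile <- function(x, ...) {
  cat(sprintf("shell_profile: %d regions, outer radius %.1f A\n",
              n_shells(x), outer_radius(x)))
  print(data.frame(r_outer = x$radii, thickness = shell_thicknesses(x),
                   contrast = x$contrasts, axial_ratio = x$axial_ratios))
  invisible(x)
}

#' @rdname shell_profile
#' @param profile a `shell_profile`.
#' @export
n_shells <- function(profile) length(profile$radii)

#' @rdname shell_profile
#' @export
outer_radius <- function(profile) profile$radii[n_shells(profile)]

#' Region thicknesses of a shell profile
#'
#' Thickness of each region; the first is the core radius itself.
#'
#' @param profile a `shell_profile`.
#' @return numeric vector of thicknesses (\eqn{\mathrm{\AA}}).
#' @export
shell_thicknesses <- function(profile) diff(c(0, profile$radii))

#' @rdname shell_profile
#' @export
is_spherical <- function(profile) all(profile$axial_ratios == 1)

#' Replace the contrast of the innermost region (water pool)
#'
#' Protein occlusion is modeled as raising the water-pool contrast from 0 to
#' a positive value; this helper substitutes that single contrast.
#'
#' @param profile a `shell_profile`.
#' @param contrast new core contrast (relative units).
#' @return modified `shell_profile`.
#' @export
set_core_contrast <- function(profile, contrast) {
  if (!is_number(contrast)) abort_luvsaxs("contrast must be a number",
                                          "invalid_profile")
  profile$contrasts[1] <- contrast
  profile
}

#' Realize a profile at a given overall radius
#'
#' Maps the template profile to a particle of outer radius `R`. In
#' `"fixed_thickness"` mode (default) the wall-region thicknesses are held
#' fixed and the water-pool radius absorbs the size change, reflecting that
#' the bilayer thickness does not vary with vesicle size; `"proportional"`
#' rescales all radii by `R / outer_radius(profile)` and is provided for
#' sensitivity checks.
#'
#' @param profile template `shell_profile`.
#' @param R target outer radius (\eqn{\mathrm{\AA}}).
#' @param mode `"fixed_thickness"` or `"proportional"`.
#' @return a `shell_profile` with outer radius `R`.
#' @export
profile_at_radius <- function(profile, R,
                              mode = c("fixed_thickness", "proportional")) {
  mode <- match.arg(mode)
  if (!is_number(R) || R <= 0)
    abort_luvsaxs("R must be a positive number", "invalid_configuration")
  if (mode == "proportional") {
    profile$radii <- profile$radii * (R / outer_radius(profile))
    return(profile)
  }
  wall <- outer_radius(profile) - profile$radii[1]
  core <- R - wall
  if (core <= 0)
    abort_luvsaxs(sprintf(
      "overall radius %.1f A smaller than total wall thickness %.1f A",
      R, wall), "invalid_configuration")
  profile$radii <- core + c(0, cumsum(shell_thicknesses(profile)[-1]))
  profile
}

#' Scattering amplitude of a spherical multi-shell particle
#'
#' Amplitude of concentric spherical regions in the annular-region
#' convention: each region contributes its own contrast times the difference
#' of consecutive solid-sphere amplitudes,
#' \deqn{A(q) = \sum_i \bar{\Delta\rho}_i \left[V(r_i)\Phi(q r_i) -
#'   V(r_{i-1})\Phi(q r_{i-1})\right],}
#' with \eqn{V(r) = (4/3)\pi r^3}, \eqn{\Phi(x) = 3 j_1(x)/x} and
#' \eqn{r_0 = 0}. At \eqn{q = 0} this is the total excess scattering mass
#' \eqn{\sum_i \bar{\Delta\rho}_i (V(r_i) - V(r_{i-1}))}.
#'
#' @param profile a spherical `shell_profile` (all axial ratios 1).
#' @param q scattering vector magnitude(s), \eqn{\mathrm{\AA}^{-1}},
#'   \eqn{q \ge 0}.
#' @return amplitude (relative units \eqn{\times \mathrm{\AA}^3}), same
#'   length as `q`.
#' @export
shell_amplitude <- function(profile, q) {
  if (!inherits(profile, "shell_profile"))
    abort_luvsaxs("profile must be a shell_profile", "invalid_profile")
  if (!is_spherical(profile))
    abort_luvsaxs("shell_amplitude requires a spherical profile (all axial ratios 1)",
                  "invalid_profile")
  if (any(q < 0)) abort_luvsaxs("q must be nonnegative", "domain_error")
  .shell_amplitude_radii(profile$radii, profile$contrasts, q)
}

# amplitude for explicit radii (no class checks) -- inner kernel shared by
# the spherical and orientation-averaged paths. For ellipsoids the boundary
# volumes stay the true ellipsoid volumes (nu * (4/3) pi r^3); only the
# form-amplitude argument picks up the orientation-dependent effective
# radius, so `volumes` can be passed separately.
.shell_amplitude_radii <- function(radii, contrasts, q,
                                   volumes = sphere_volume(radii)) {
  x <- outer(q, radii)
  term <- sweep(sphere_form_amplitude(x), 2, volumes, `*`)
  n <- length(radii)
  prev <- cbind(0, term[, -n, drop = FALSE])
  drop((term - prev) %*% contrasts)
}

#' Orientationally averaged intensity of a single particle
#'
#' \eqn{I_s(q, R)} of a multi-shell ellipsoidal particle. For a spherical
#' profile this is exactly `shell_amplitude(profile, q)^2`. For ellipsoidal
#' regions (\eqn{\nu_i \ne 1}) the orientation average
#' \deqn{I_s(q) = \int_0^1 \left|A\big(q;\, r_1(x) \dots r_n(x)\big)\right|^2 dx,
#'   \quad r_i(x) = r_i\sqrt{1 + x^2(\nu_i^2 - 1)},}
#' is evaluated by fixed-order Gauss-Legendre quadrature on
#' \eqn{x \in [0, 1]}. In the amplitude the boundary volumes remain the true
#' ellipsoid volumes \eqn{\nu_i (4/3)\pi r_i^3}; only the argument of
#' \eqn{\Phi} carries the orientation-dependent effective radius, so the
#' forward limit \eqn{I(0)} is independent of the axial ratios.
#'
#' @param profile a `shell_profile`.
#' @param q scattering vector magnitude(s) (\eqn{\mathrm{\AA}^{-1}}).
#' @param n_orient quadrature order for the orientation average (ellipsoidal
#'   profiles only).
#' @param force_orientational evaluate the orientation-average quadrature
#'   even for a spherical profile (for which the closed spherical form is
#'   normally used); intended for verifying that the two routes agree.
#' @return intensity (arbitrary units, nonnegative), same length as `q`.
#' @export
intensity_monodisperse <- function(profile, q, n_orient = 64,
                                   force_orientational = FALSE) {
  if (!inherits(profile, "shell_profile"))
    abort_luvsaxs("profile must be a shell_profile", "invalid_profile")
  if (any(q < 0)) abort_luvsaxs("q must be nonnegative", "domain_error")
  if (is_spherical(profile) && !force_orientational)
    return(shell_amplitude(profile, q)^2)
  gl <- gauss_legendre(n_orient, 0, 1)
  nu2 <- profile$axial_ratios^2
  vols <- profile$axial_ratios * sphere_volume(profile$radii)
  out <- numeric(length(q))
  for (k in seq_along(gl$x)) {
    rk <- profile$radii * sqrt(1 + gl$x[k]^2 * (nu2 - 1))
    out <- out + gl$w[k] *
      .shell_amplitude_radii(rk, profile$contrasts, q, volumes = vols)^2
  }
  out
}

#' Truncated-Gaussian size distribution of the overall particle radius
#'
#' Number distribution \eqn{D(R)}: a Gaussian with mean `mean_radius` and
#' standard deviation `sigma`, truncated below at `r_min` (the smallest
#' radius a vesicle can have, set by its wall thickness) and renormalized to
#' unit integral on \eqn{[R_{\min}, \infty)}.
#'
#' @param mean_radius mean radius \eqn{\bar R} (\eqn{\mathrm{\AA}}).
#' @param sigma standard deviation (\eqn{\mathrm{\AA}}); give either this or
#'   `sigma_percent`.
#' @param sigma_percent standard deviation as percent of `mean_radius`.
#' @param r_min lower truncation radius (\eqn{\mathrm{\AA}}).
#' @return an object of class `size_distribution`.
#' @export
size_distribution <- function(mean_radius, sigma = NULL, sigma_percent = NULL,
                              r_min = 0) {
  if (!is_number(mean_radius) || mean_radius <= 0)
    abort_luvsaxs("mean_radius must be positive", "invalid_configuration")
  if (is.null(sigma)) {
    if (is.null(sigma_percent))
      abort_luvsaxs("give sigma or sigma_percent", "invalid_configuration")
    sigma <- mean_radius * sigma_percent / 100
  }
  if (!is_number(sigma) || sigma < 0)
    abort_luvsaxs("sigma must be nonnegative", "invalid_configuration")
  if (!is_number(r_min) || r_min < 0)
    abort_luvsaxs("r_min must be nonnegative", "invalid_configuration")
  structure(list(mean_radius = mean_radius, sigma = sigma, r_min = r_min),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("size_distribution: mean %.1f A, sigma %.1f A (%.1f%%), r_min %.1f A\n",
              x$mean_radius, x$sigma, 100 * x$sigma / x$mean_radius, x$r_min))
  invisible(x)
}

#' Density of the truncated-Gaussian number distribution
#'
#' @param dist a `size_distribution`.
#' @param R radius (\eqn{\mathrm{\AA}}), vectorized. Values below
#'   `dist$r_min` have zero density.
#' @return density (\eqn{\mathrm{\AA}^{-1}}). With `sigma = 0` the
#'   distribution degenerates to a point mass at the mean: the density is
#'   `Inf` at `mean_radius` and 0 elsewhere.
#' @export
gaussian_number_distribution <- function(dist, R) {
  if (!inherits(dist, "size_distribution"))
    abort_luvsaxs("dist must be a size_distribution", "invalid_configuration")
  if (dist$sigma == 0)
    return(ifelse(R == dist$mean_radius, Inf, 0))
  z <- stats::pnorm(dist$r_min, dist$mean_radius, dist$sigma, lower.tail = FALSE)
  ifelse(R < dist$r_min, 0,
         stats::dnorm(R, dist$mean_radius, dist$sigma) / z)
}

#' Draw radii from the size distribution by inverse-CDF sampling
#'
#' @param dist a `size_distribution`.
#' @param n number of draws.
#' @return numeric vector of radii \eqn{\ge} `r_min`.
#' @export
sample_size_distribution <- function(dist, n) {
  if (dist$sigma == 0) return(rep(dist$mean_radius, n))
  f_min <- stats::pnorm(dist$r_min, dist$mean_radius, dist$sigma)
  u <- stats::runif(n, f_min, 1)
  stats::qnorm(u, dist$mean_radius, dist$sigma)
}

# Quadrature nodes (radius, weight x density) covering the size distribution.
size_quadrature <- function(dist, n_nodes = 201) {
  if (dist$sigma == 0)
    return(list(R = dist$mean_radius, w = 1))
  upper <- dist$mean_radius + 6 * dist$sigma
  gl <- gauss_legendre(n_nodes, dist$r_min, upper)
  list(R = gl$x, w = gl$w * gaussian_number_distribution(dist, gl$x))
}

#' Polydispersity-integrated scattering intensity
#'
#' \deqn{I(q) = \int_{R_{\min}}^{\infty} D(R)\, I_s(q, R)\, dR,}
#' where \eqn{D(R)} is the truncated-Gaussian number distribution and
#' \eqn{I_s(q, R)} the single-particle intensity of the profile realized at
#' overall radius \eqn{R} (see [profile_at_radius()]; by default wall
#' thicknesses stay fixed and the water-pool radius varies). The radial
#' integral uses Gauss-Legendre quadrature on
#' \eqn{[R_{\min}, \bar R + 6\sigma]}.
#'
#' @param profile template `shell_profile`; its own outer radius is replaced
#'   by the quadrature radius.
#' @param dist a `size_distribution`. `r_min` must exceed the total wall
#'   thickness so that every realized particle has a positive core.
#' @param q scattering vector magnitudes (\eqn{\mathrm{\AA}^{-1}}).
#' @param n_nodes radial quadrature order (default 201).
#' @param mode polydispersity convention, see [profile_at_radius()].
#' @param n_orient orientation-average order for ellipsoidal profiles.
#' @return intensity (arbitrary units), same length as `q`.
#' @export
intensity_polydisperse <- function(profile, dist, q, n_nodes = 201,
                                   mode = c("fixed_thickness", "proportional"),
                                   n_orient = 64) {
  mode <- match.arg(mode)
  if (!inherits(dist, "size_distribution"))
    abort_luvsaxs("dist must be a size_distribution", "invalid_configuration")
  wall <- outer_radius(profile) - profile$radii[1]
  if (mode == "fixed_thickness" && dist$sigma > 0 && dist$r_min <= wall)
    abort_luvsaxs(sprintf(
      "r_min (%.1f A) must exceed the total wall thickness (%.1f A)",
      dist$r_min, wall), "invalid_configuration")
  quad <- size_quadrature(dist, n_nodes)
  radii_at <- function(R) profile_at_radius(profile, R, mode)$radii
  if (is_spherical(profile)) {
    rmat <- vapply(quad$R, radii_at, numeric(n_shells(profile)))
    return(.batch_intensity_spherical(t(rmat), profile$contrasts, q, quad$w))
  }
  out <- numeric(length(q))
  for (k in seq_along(quad$R)) {
    pk <- profile_at_radius(profile, quad$R[k], mode)
    out <- out + quad$w[k] * intensity_monodisperse(pk, q, n_orient)
  }
  out
}

# weighted sum of squared amplitudes over many spherical realizations at
# once: rmat is K x n (rows = realizations), w the quadrature weights.
# Same annular-region amplitude as .shell_amplitude_radii, vectorized over
# realizations.
.batch_intensity_spherical <- function(rmat, contrasts, q, w) {
  K <- nrow(rmat); n <- ncol(rmat)
  rv <- as.vector(rmat)                       # boundary-major blocks of K
  term <- sphere_form_amplitude(outer(q, rv)) *
    rep(sphere_volume(rv), each = length(q))
  dim(term) <- c(length(q), K, n)
  A <- matrix(contrasts[1] * term[, , 1], nrow = length(q))
  if (n > 1) for (i in 2:n)
    A <- A + contrasts[i] * (term[, , i] - term[, , i - 1])
  drop(A^2 %*% w)
}

#' Closed-form radius of gyration of a spherical shell profile
#'
#' For a piecewise-constant spherical density,
#' \deqn{R_g^2 = \frac{3}{5}\,
#'   \frac{\sum_i \bar{\Delta\rho}_i (r_i^5 - r_{i-1}^5)}
#'        {\sum_i \bar{\Delta\rho}_i (r_i^3 - r_{i-1}^3)}.}
#' Used as the analytic oracle for Guinier fits of model curves.
#'
#' @param profile a spherical `shell_profile`.
#' @param at_radius optional overall radius at which to realize the profile
#'   first (see [profile_at_radius()]).
#' @param mode polydispersity convention used when `at_radius` is given.
#' @return radius of gyration (\eqn{\mathrm{\AA}}).
#' @export
analytic_rg <- function(profile, at_radius = NULL,
                        mode = c("fixed_thickness", "proportional")) {
  if (!is_spherical(profile))
    abort_luvsaxs("analytic_rg requires a spherical profile", "invalid_profile")
  if (!is.null(at_radius))
    profile <- profile_at_radius(profile, at_radius, match.arg(mode))
  r <- profile$radii
  r0 <- c(0, r[-length(r)])
  num <- sum(profile$contrasts * (r^5 - r0^5))
  den <- sum(profile$contrasts * (r^3 - r0^3))
  if (abs(den) < 1e-12 * sum(abs(profile$contrasts) * r^3))
    abort_luvsaxs("net excess scattering mass is zero; Rg undefined",
                  "undefined_rg")
  rg2 <- 0.6 * num / den
  if (rg2 <= 0)
    abort_luvsaxs("negative Rg^2; profile has no defined Guinier radius",
                  "undefined_rg")
  sqrt(rg2)
}
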