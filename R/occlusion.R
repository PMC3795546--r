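# Protein-occlusion analysis: sweep the water-pool contrast, build the
# Rg-concentration relation, and invert a measured Rg decrement into an
# encapsulated protein concentration.

#' Physical constants for the contrast-concentration bridge
#'
#' X-ray scattering densities of water and protein, and the protein partial
#' specific volume, used to convert between encapsulated protein
#' concentration, water-pool volume fraction and water-pool contrast.
#' Protein scattering densities for X-rays span about 11.7--12.0 in units
#' of \eqn{10^{10}\,\mathrm{cm}^{-2}}; the default is the midpoint. The
#' default partial specific volume 0.73 \eqn{\mathrm{cm^3\,g^{-1}}} is
#' typical for globular proteins.
#'
#' @param rho_water water scattering density (\eqn{10^{10}\,\mathrm{cm}^{-2}}).
#' @param rho_protein protein scattering density (same units).
#' @param v_bar protein partial specific volume (\eqn{\mathrm{cm^3\,g^{-1}}}),
#'   must lie in (0.6, 0.85).
#' @return an object of class `physical_constants`.
#' @export
physical_constants <- function(rho_water = 9.38, rho_protein = 11.85,
                               v_bar = 0.73) {
  if (rho_protein <= rho_water)
    abort_luvsaxs("rho_protein must exceed rho_water", "domain_error")
  if (v_bar <= 0.6 || v_bar >= 0.85)
    abort_luvsaxs("v_bar must lie in (0.6, 0.85) cm^3/g", "domain_error")
  structure(list(rho_water = rho_water, rho_protein = rho_protein,
                 v_bar = v_bar), class = "physical_constants")
}

#' Water-pool contrast from protein volume fraction
#'
#' Protein occupying a volume fraction \eqn{\phi} of the water pool raises
#' the pool's average excess scattering density to
#' \eqn{\phi\,(\rho_p - \rho_w)}, in relative units of
#' \eqn{10^{10}\,\mathrm{cm}^{-2}}. Full occupancy with
#' \eqn{\rho_p = 12.0} gives \eqn{2.62 \approx 2.6}.
#'
#' @param phi protein volume fraction of the water pool, in \eqn{[0, 1]}.
#' @param constants a [physical_constants()].
#' @return contrast (relative units), vectorized over `phi`.
#' @export
core_contrast_from_volume_fraction <- function(phi,
                                               constants = physical_constants()) {
  if (any(phi < 0 | phi > 1))
    abort_luvsaxs("phi must lie in [0, 1]", "domain_error")
  phi * (constants$rho_protein - constants$rho_water)
}

#' Protein volume fraction from % w/v concentration
#'
#' A concentration of `c_wv` grams of protein per 100 mL of water pool
#' occupies the volume fraction \eqn{\phi = c_{wv}\,\bar v / 100}.
#'
#' @param c_wv concentration in % w/v (g per 100 mL of pool).
#' @param constants a [physical_constants()].
#' @return volume fraction, vectorized over `c_wv`.
#' @export
concentration_to_volume_fraction <- function(c_wv,
                                             constants = physical_constants()) {
  if (any(c_wv < 0))
    abort_luvsaxs("concentration must be nonnegative", "domain_error")
  phi <- c_wv * constants$v_bar / 100
  if (any(phi > 1))
    abort_luvsaxs("concentration exceeds water-pool saturation (phi > 1)",
                  "over_saturation")
  phi
}

#' Sweep the water-pool contrast of a vesicle model
#'
#' For each contrast value, substitutes it into the water pool (region 1),
#' computes the polydisperse model curve, its Guinier radius of gyration and
#' its p(r) peak position. This simulates increasing protein occlusion at
#' fixed vesicle geometry.
#'
#' @param profile template [shell_profile()] (region 1 = water pool).
#' @param dist a [size_distribution()].
#' @param contrasts ascending nonnegative contrast values (default 27 nodes
#'   on \eqn{[0, 2.6]}).
#' @param q q grid for the model curves; must reach low enough q for the
#'   Guinier window of the largest Rg in the sweep.
#' @param keep_curves keep the model curves in the result (memory permitting).
#' @param qrg_max Guinier window bound.
#' @param n_nodes radial quadrature order.
#' @param pr_r_max,pr_dr real-space grid for p(r).
#' @return an object of class `contrast_sweep`: data frame with columns
#'   `contrast`, `rg`, `pr_peak`, plus attribute `curves` (list of
#'   [scattering_curve()], if kept).
#' @export
rg_contrast_sweep <- function(profile, dist,
                              contrasts = seq(0, 2.6, length.out = 27),
                              q = default_q_grid(), keep_curves = FALSE,
                              qrg_max = 1.0, n_nodes = 201,
                              pr_r_max = 2000, pr_dr = 2) {
  if (any(contrasts < 0) || any(diff(contrasts) < 0))
    abort_luvsaxs("contrasts must be nonnegative and ascending", "domain_error")
  r_grid <- seq(0, pr_r_max, by = pr_dr)
  rows <- vector("list", length(contrasts))
  curves <- if (keep_curves) vector("list", length(contrasts)) else NULL
  for (i in seq_along(contrasts)) {
    p_i <- set_core_contrast(profile, contrasts[i])
    cv <- model_curve(p_i, dist, q = q, n_nodes = n_nodes)
    g <- guinier_fit(cv, qrg_max = qrg_max)
    dd <- distance_distribution(cv, r_grid = r_grid)
    rows[[i]] <- data.frame(contrast = contrasts[i], rg = g$rg,
                            pr_peak = attr(dd, "peak_position"))
    if (keep_curves) curves[[i]] <- cv
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  class(out) <- c("contrast_sweep", "data.frame")
  out
}

#' Build the encapsulation-efficiency relation
#'
#' Composes concentration \eqn{\to} volume fraction \eqn{\to} water-pool
#' contrast \eqn{\to} model Rg, and normalizes each Rg against the empty
#' (c = 0) value to give the decrement rate
#' \eqn{(R_g^{\mathrm{empty}} - R_g^{\mathrm{filled}})/R_g^{\mathrm{empty}}}
#' on a grid of encapsulated protein concentrations.
#'
#' @param profile,dist vesicle model (region 1 = water pool).
#' @param constants a [physical_constants()].
#' @param c_grid ascending concentration grid starting at 0 (% w/v).
#' @param ... passed to [rg_contrast_sweep()].
#' @return an object of class `efficiency_relation`: data frame with columns
#'   `concentration`, `contrast`, `rg`, `decrement`, with `constants` kept
#'   as an attribute.
#' @export
build_efficiency_relation <- function(profile, dist,
                                      constants = physical_constants(),
                                      c_grid = seq(0, 12, by = 0.5), ...) {
  if (c_grid[1] != 0 || any(diff(c_grid) <= 0))
    abort_luvsaxs("c_grid must ascend from 0", "domain_error")
  phi <- concentration_to_volume_fraction(c_grid, constants)
  contrasts <- core_contrast_from_volume_fraction(phi, constants)
  sweep <- rg_contrast_sweep(profile, dist, contrasts = contrasts, ...)
  rg0 <- sweep$rg[1]
  dec <- (rg0 - sweep$rg) / rg0
  if (any(diff(dec) < -1e-6))
    abort_luvsaxs(paste("Rg decrement is not monotone over the grid;",
                        "increase the radial quadrature order (n_nodes)"),
                  "resolution_error")
  out <- data.frame(concentration = c_grid, contrast = contrasts,
                    rg = sweep$rg, decrement = dec)
  attr(out, "constants") <- constants
  class(out) <- c("efficiency_relation", "data.frame")
  out
}

#' Estimate the encapsulated protein concentration from measured Rg values
#'
#' Inverts the efficiency relation at the measured decrement rate
#' \eqn{(R_g^{\mathrm{empty}} - R_g^{\mathrm{filled}})/R_g^{\mathrm{empty}}}
#' by monotone interpolation of decrement versus water-pool contrast, then
#' converts the contrast back to % w/v. Because the model Rg depends only on
#' the contrast, a sensitivity band over the protein scattering density and
#' partial specific volume is obtained by re-converting the same contrast
#' under the extreme constants.
#'
#' @param rg_empty,rg_filled measured radii of gyration
#'   (\eqn{\mathrm{\AA}}), \eqn{0 < R_g^{filled} \le R_g^{empty}}.
#' @param relation an [build_efficiency_relation()] result.
#' @param rho_protein_range,v_bar_range ranges for the sensitivity band.
#' @return list with `concentration` (% w/v), `band` (range under the
#'   constant ranges), `decrement`, `contrast`.
#' @export
estimate_encapsulated_concentration <- function(rg_empty, rg_filled, relation,
                                                rho_protein_range = c(11.7, 12.0),
                                                v_bar_range = c(0.70, 0.75)) {
  if (!is_number(rg_empty) || !is_number(rg_filled) ||
      rg_filled <= 0 || rg_filled > rg_empty)
    abort_luvsaxs("need 0 < rg_filled <= rg_empty", "domain_error")
  dec <- (rg_empty - rg_filled) / rg_empty
  if (dec > max(relation$decrement))
    abort_luvsaxs(sprintf(
      "decrement %.3f beyond the tabulated maximum %.3f; extend c_grid",
      dec, max(relation$decrement)), "out_of_range")
  contrast <- stats::approx(relation$decrement, relation$contrast, xout = dec,
                            ties = "ordered")$y
  constants <- attr(relation, "constants")
  to_conc <- function(rho_p, v_bar)
    100 * contrast / ((rho_p - constants$rho_water) * v_bar)
  conc <- to_conc(constants$rho_protein, constants$v_bar)
  corners <- expand.grid(rho = rho_protein_range, v = v_bar_range)
  band <- range(mapply(to_conc, corners$rho, corners$v))
  list(concentration = conc, band = band, decrement = dec, contrast = contrast)
}
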