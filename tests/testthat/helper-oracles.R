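# Independent oracles used across the suite. Each recomputes a quantity by
# a route different from the implementation under test.

# piecewise-constant radial density of a spherical shell profile
profile_density_at <- function(profile, r) {
  idx <- findInterval(r, profile$radii, left.open = TRUE) + 1L
  out <- numeric(length(r))
  inside <- idx <= n_shells(profile)
  out[inside] <- profile$contrasts[idx[inside]]
  out
}

# brute-force radial quadrature of the amplitude:
# A(q) = 4 pi int rho(r) r^2 sin(qr)/(qr) dr, midpoint rule with ~n points
# distributed over the regions so that nodes never straddle a density jump
oracle_amplitude_quadrature <- function(profile, q, n = 1e4) {
  edges <- c(0, profile$radii)
  widths <- diff(edges)
  n_i <- pmax(16L, ceiling(n * widths / sum(widths)))
  out <- numeric(length(q))
  for (i in seq_along(widths)) {
    dr <- widths[i] / n_i[i]
    r <- edges[i] + (seq_len(n_i[i]) - 0.5) * dr
    rho <- profile$contrasts[i]
    out <- out + vapply(q, function(qi) {
      kern <- if (qi == 0) rep(1, length(r)) else sin(qi * r) / (qi * r)
      4 * pi * rho * sum(r^2 * kern) * dr
    }, 1)
  }
  out
}

# boundary-difference convention for the same amplitude (algebraically
# identical bookkeeping of the piecewise-constant density)
oracle_amplitude_boundary <- function(profile, q) {
  rho <- profile$contrasts
  drho <- rho - c(rho[-1], 0)           # density step at each boundary
  r <- profile$radii
  out <- numeric(length(q))
  for (j in seq_along(r))
    out <- out + drho[j] * sphere_volume(r[j]) *
      sphere_form_amplitude(q * r[j])
  out
}

# dense-trapezoid orientational average for ellipsoidal shells, written in
# the boundary-difference convention with true ellipsoid volumes
oracle_intensity_ellipsoid <- function(profile, q, n = 1e5) {
  x <- seq(0, 1, length.out = n)
  nu2 <- profile$axial_ratios^2
  rho <- profile$contrasts
  drho <- rho - c(rho[-1], 0)
  vols <- profile$axial_ratios * sphere_volume(profile$radii)
  acc <- numeric(length(q))
  w <- c(0.5, rep(1, n - 2), 0.5) / (n - 1)
  for (k in seq_len(n)) {
    rk <- profile$radii * sqrt(1 + x[k]^2 * (nu2 - 1))
    a <- numeric(length(q))
    for (j in seq_along(rk))
      a <- a + drho[j] * vols[j] * sphere_form_amplitude(q * rk[j])
    acc <- acc + w[k] * a^2
  }
  acc
}

# real-space autocorrelation oracle for p(r) of a spherically symmetric
# particle, normalized so that I(q) = 4 pi int p(r) sinc(qr) dr:
# p(r) = 2 pi r int_0^inf u rho(u) [ F(r+u) - F(|r-u|) ] du,
# with F(v) = int_0^v t rho(t) dt
oracle_pr_autocorrelation <- function(profile, r_grid, du = 0.25) {
  rmax <- outer_radius(profile)
  u <- seq(du / 2, rmax, by = du)
  rho_u <- profile_density_at(profile, u)
  # cumulative table F(v) = int_0^v t rho(t) dt on a fine grid
  vg <- seq(0, rmax, by = du / 2)
  integrand <- vg * profile_density_at(profile, vg)
  cumF <- cumsum((integrand + c(0, integrand[-length(integrand)])) / 2) *
    (du / 2)
  Fcum <- function(v)
    approx(vg, cumF, xout = pmin(pmax(v, 0), rmax), rule = 2)$y
  vapply(r_grid, function(r) {
    if (r <= 0) return(0)
    inner <- Fcum(r + u) - Fcum(abs(r - u))
    2 * pi * r * sum(u * rho_u * inner) * du
  }, 1)
}

# analytic p(r) of a uniform solid sphere of radius R (unit density),
# normalized so that I(q) = 4 pi int p(r) sinc(qr) dr:
# p(r) = r^2 V gamma(r), gamma(r) = 1 - (3/4)(r/R) + (1/16)(r/R)^3
oracle_pr_solid_sphere <- function(R, r) {
  x <- r / R
  ifelse(r < 0 | r > 2 * R, 0,
         r^2 * sphere_volume(R) * (1 - 0.75 * x + x^3 / 16))
}

# intensity-weighted (z-average) Rg of a polydisperse spherical model from
# closed-form moments of the truncated-Gaussian distribution
oracle_polydisperse_rg <- function(profile, dist, n_nodes = 801) {
  upper <- dist$mean_radius + 6 * dist$sigma
  R <- seq(dist$r_min, upper, length.out = n_nodes)
  w <- gaussian_number_distribution(dist, R)
  i0 <- rg2 <- numeric(length(R))
  for (k in seq_along(R)) {
    pk <- profile_at_radius(profile, R[k])
    rr <- pk$radii; r0 <- c(0, rr[-length(rr)])
    i0[k] <- sum(pk$contrasts * (rr^3 - r0^3))^2
    rg2[k] <- analytic_rg(pk)^2
  }
  sqrt(sum(w * i0 * rg2) / sum(w * i0))
}

# random valid spherical profiles for property tests
random_profile <- function(n_regions = sample(1:6, 1), positive_mass = FALSE) {
  repeat {
    radii <- sort(stats::runif(n_regions, 30, 500))
    if (any(diff(radii) < 5)) next
    contrasts <- stats::runif(n_regions, -3, 3)
    if (positive_mass) contrasts <- abs(contrasts)
    p <- shell_profile(radii, contrasts)
    r0 <- c(0, radii[-n_regions])
    den <- sum(contrasts * (radii^3 - r0^3))
    num <- sum(contrasts * (radii^5 - r0^5))
    # keep the net mass away from zero so Rg and I(0) are well conditioned
    if (abs(den) > 0.05 * sum(abs(contrasts) * (radii^3 - r0^3)) &&
        num / den > 0) return(p)
  }
}

# q grid spanning the Guinier regime of a given Rg
guinier_q_grid <- function(rg, n = 120) {
  exp(seq(log(0.03 / rg), log(2.5 / rg), length.out = n))
}
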