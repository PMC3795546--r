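solid_sphere_curve <- function(R = 400, q = 10^seq(-4, log10(0.5), length.out = 1500)) {
  # dense log grid; switch to uniform above 0.01 to keep dq small for the FT
  q_lo <- q[q < 0.01]
  q_hi <- seq(0.01, max(q), length.out = 1200)
  qq <- c(q_lo, q_hi)
  scattering_curve(qq, intensity_monodisperse(shell_profile(R, 1), qq))
}

test_that("p(r) of a solid sphere peaks near 1.05 R and matches the closed form", {
  R <- 400
  cv <- solid_sphere_curve(R)
  dd <- distance_distribution(cv, r_grid = seq(0, 1000, by = 1))
  # oracle: maximum of the analytic p(r) located numerically
  r_star <- optimize(function(r) -oracle_pr_solid_sphere(R, r),
                     c(R / 2, 2 * R))$minimum
  expect_equal(r_star / R, 1.05, tolerance = 0.005)
  expect_equal(attr(dd, "peak_position"), r_star, tolerance = 0.02)
  # shape agreement away from the truncation-affected origin
  sel <- dd$r > 50 & dd$r < 780
  ref <- oracle_pr_solid_sphere(R, dd$r[sel])
  expect_lt(max(abs(dd$p[sel] - ref)) / max(ref), 0.02)
  # nonnegative real-space structure: no ripple
  expect_equal(attr(dd, "ripple_extent"), 0)
})

test_that("p(r) is linear in the intensity and zero for zero intensity", {
  cv1 <- solid_sphere_curve(300)
  cv2 <- solid_sphere_curve(150)    # same grid construction
  q <- cv1$q
  cv_sum <- scattering_curve(q, cv1$I + cv2$I)
  r_grid <- seq(0, 800, by = 2)
  p1 <- distance_distribution(cv1, r_grid)$p
  p2 <- distance_distribution(cv2, r_grid)$p
  ps <- distance_distribution(cv_sum, r_grid)$p
  expect_equal(ps, p1 + p2, tolerance = 1e-10)
  cv0 <- scattering_curve(q, rep(0, length(q)))
  expect_true(all(distance_distribution(cv0, r_grid)$p == 0))
})

test_that("p(r) of the monodisperse empty-vesicle wall matches the real-space autocorrelation", {
  fx <- canonical_fixture()
  # q_max = 1 resolves the sharp wall-correlation peak; taper off for a
  # clean quantitative comparison
  q <- c(10^seq(-4, -2, length.out = 150), seq(0.0102, 1.0, length.out = 3700))
  cv <- scattering_curve(q, intensity_monodisperse(fx$profile, q))
  r_grid <- seq(0, 900, by = 1)
  dd <- distance_distribution(cv, r_grid, taper = FALSE)
  ref <- oracle_pr_autocorrelation(fx$profile, r_grid, du = 0.25)
  i_ref <- which.max(ref)
  expect_equal(attr(dd, "peak_position"), r_grid[i_ref], tolerance = 0.02)
  expect_equal(max(dd$p), max(ref), tolerance = 0.02)
})

test_that("a too-sparse q grid raises an aliasing error", {
  q <- seq(0.01, 0.3, by = 0.01)
  cv <- scattering_curve(q, exp(-q^2 * 1e4))
  expect_error(distance_distribution(cv, r_grid = seq(0, 2000, by = 2)),
               class = "luvsaxs_aliasing")
})

test_that("transform round trip reproduces the intensity on the interior q range", {
  fx <- canonical_fixture()
  # dense grid: the trapezoid forward transform must resolve the integrand
  # well for its inverse to close to within 1%
  q <- c(10^seq(log10(3e-4), log10(3e-3), length.out = 300)[-300],
         seq(3e-3, 0.3, length.out = 1800))
  cv <- model_curve(fx$profile, fx$dist, q = q)
  dd <- distance_distribution(cv, r_grid = seq(0, 2400, by = 2),
                              taper = FALSE)
  q_int <- cv$q[cv$q >= 2e-3 & cv$q <= 0.1]
  rec <- intensity_from_pr(dd, q_int)
  orig <- cv$I[match(q_int, cv$q)]
  expect_lt(max(abs(rec$I - orig) / orig), 0.01)
})

test_that("Guinier fit reproduces closed-form radii for spheres and thin shells", {
  R <- 400
  p <- shell_profile(R, 1)
  q <- guinier_q_grid(sqrt(3 / 5) * R)
  g <- guinier_fit(scattering_curve(q, intensity_monodisperse(p, q)))
  # the q.Rg <= 1 window carries a small positive bias from Guinier-law
  # curvature, so agreement is at the percent level, not exact
  expect_equal(g$rg, sqrt(3 / 5) * R, tolerance = 0.015)
  expect_equal(g$i0, sphere_volume(R)^2, tolerance = 0.01)
  thin <- vesicle_profile(398, 2, 1, core_contrast = 0)
  q2 <- guinier_q_grid(400)
  g2 <- guinier_fit(scattering_curve(q2, intensity_monodisperse(thin, q2)))
  expect_equal(g2$rg, analytic_rg(thin), tolerance = 0.02)
})

test_that("Guinier fit agrees with closed-form Rg over random shell profiles", {
  set.seed(21)
  err <- replicate(50, {
    p <- random_profile(positive_mass = TRUE)
    rg <- analytic_rg(p)
    q <- guinier_q_grid(rg)
    g <- guinier_fit(scattering_curve(q, intensity_monodisperse(p, q)))
    abs(g$rg - rg) / rg
  })
  expect_lt(max(err), 0.02)
})

test_that("Guinier fit of the polydisperse fixture matches the moment oracle", {
  fx <- canonical_fixture()
  cv <- model_curve(fx$profile, fx$dist)
  g <- guinier_fit(cv)
  rg_z <- oracle_polydisperse_rg(fx$profile, fx$dist)
  expect_equal(g$rg, rg_z, tolerance = 0.02)
})

test_that("rising intensity yields a no-Guinier-regime error", {
  q <- seq(1e-3, 0.01, length.out = 50)
  cv <- scattering_curve(q, exp(+q^2 * 1e5))
  expect_error(guinier_fit(cv), class = "luvsaxs_no_guinier_regime")
})

test_that("weighted Guinier fit honors the uncertainty column", {
  R <- 250
  p <- shell_profile(R, 1)
  q <- guinier_q_grid(sqrt(3 / 5) * R)
  I <- intensity_monodisperse(p, q)
  cv <- scattering_curve(q, I, sigma = 0.01 * I)
  g <- guinier_fit(cv)
  expect_equal(g$rg, sqrt(3 / 5) * R, tolerance = 0.015)
  expect_true(is.finite(g$rg_stderr))
})

test_that("bilayer ripple is detected in the empty vesicle and damped when filled", {
  fx <- canonical_fixture()
  cv0 <- model_curve(fx$profile, fx$dist)
  cv26 <- model_curve(set_core_contrast(fx$profile, 2.6), fx$dist)
  dd0 <- distance_distribution(cv0)
  dd26 <- distance_distribution(cv26)
  ext <- attr(dd0, "ripple_extent")
  expect_gte(ext, 40)
  expect_lte(ext, 70)
  # normalized oscillation amplitude below 55 A shrinks upon filling
  osc <- function(dd) {
    sel <- dd$r > 0 & dd$r <= 55
    (max(dd$p[sel]) - min(dd$p[sel])) / max(dd$p)
  }
  expect_lt(osc(dd26), osc(dd0))
})
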