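test_that("profile constructors validate geometry", {
  expect_s3_class(shell_profile(c(100, 150), c(1, -1)), "shell_profile")
  expect_error(shell_profile(c(150, 100), c(1, -1)),
               class = "luvsaxs_invalid_profile")
  expect_error(shell_profile(c(100, 100), c(1, -1)),
               class = "luvsaxs_invalid_profile")
  expect_error(shell_profile(100, NaN), class = "luvsaxs_invalid_profile")
  p <- vesicle_profile(340, c(6, 9, 24, 9, 12), c(1, 2, -2, 2, 1))
  expect_equal(n_shells(p), 6)
  expect_equal(outer_radius(p), 400)
  expect_equal(shell_thicknesses(p), c(340, 6, 9, 24, 9, 12))
})

test_that("forward amplitude matches closed forms for a uniform sphere", {
  p <- shell_profile(400, 1)
  expect_equal(shell_amplitude(p, 0), sphere_volume(400))
  # smallest positive root of the amplitude sits at q r = 4.4934 (first
  # zero of j1)
  qz <- uniroot(function(q) shell_amplitude(p, q), c(4 / 400, 5 / 400),
                tol = 1e-12)$root
  expect_equal(qz * 400, 4.4934, tolerance = 1e-4)
})

test_that("amplitude agrees with radial quadrature and boundary-difference oracles", {
  set.seed(11)
  q <- c(0, 10^seq(-3, -0.7, length.out = 25))
  for (i in 1:8) {
    p <- random_profile()
    a <- shell_amplitude(p, q)
    a_bd <- oracle_amplitude_boundary(p, q)
    expect_equal(a, a_bd, tolerance = 1e-12)
    a_quad <- oracle_amplitude_quadrature(p, q, n = 1e4)
    scale <- max(abs(a))
    expect_lt(max(abs(a - a_quad)) / scale, 1e-6)
  }
})

test_that("orientational average reduces to the spherical form at axial ratio 1", {
  set.seed(12)
  q <- 10^seq(-3, -0.5, length.out = 40)
  for (i in 1:5) {
    p <- random_profile()
    ref <- shell_amplitude(p, q)^2
    got <- intensity_monodisperse(p, q, force_orientational = TRUE)
    expect_lt(max(abs(got - ref)) / max(ref), 1e-10)
  }
})

test_that("ellipsoidal intensity matches a dense-trapezoid orientation average", {
  p <- shell_profile(300, 1.2, axial_ratios = 1.5)
  q <- 10^seq(-3, -1, length.out = 20)
  got <- intensity_monodisperse(p, q)
  ref <- oracle_intensity_ellipsoid(p, q, n = 1e5)
  expect_lt(max(abs(got - ref) / ref), 1e-6)
})

test_that("I(0) equals the squared excess scattering mass regardless of shape", {
  p_sph <- vesicle_profile(200, c(20, 30), c(2, -1), core_contrast = 0.5)
  r <- p_sph$radii; r0 <- c(0, r[-3])
  mass <- sum(p_sph$contrasts * (sphere_volume(r) - sphere_volume(r0)))
  expect_equal(intensity_monodisperse(p_sph, 0), mass^2)
  # an ellipsoidal particle with the same semi-axes carries nu times the
  # volume; its forward intensity is still the squared mass, untouched by
  # the orientation average
  p_ell <- p_sph
  p_ell$axial_ratios <- c(1.4, 1.4, 1.4)
  expect_equal(intensity_monodisperse(p_ell, 0), (1.4 * mass)^2,
               tolerance = 1e-10)
})

test_that("intensity scales with the square of a global contrast factor", {
  set.seed(13)
  q <- 10^seq(-3, -0.6, length.out = 30)
  p <- random_profile(4)
  p2 <- p; p2$contrasts <- 3 * p$contrasts
  expect_equal(intensity_monodisperse(p2, q), 9 * intensity_monodisperse(p, q))
  d <- size_distribution(400, sigma_percent = 20, r_min = 150)
  pv <- vesicle_profile(340, c(30, 30), c(1, -0.5))
  pv2 <- pv; pv2$contrasts <- 3 * pv$contrasts
  expect_equal(intensity_polydisperse(pv2, d, q),
               9 * intensity_polydisperse(pv, d, q))
})

test_that("truncated Gaussian size distribution is normalized and symmetric", {
  d <- size_distribution(400, sigma = 120, r_min = 60)
  f <- function(R) gaussian_number_distribution(d, R)
  expect_equal(integrate(f, 60, 400 + 8 * 120, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  d2 <- size_distribution(400, sigma = 30, r_min = 60)  # r_min << mean - 5 sigma
  delta <- seq(5, 90, by = 5)
  expect_equal(gaussian_number_distribution(d2, 400 - delta),
               gaussian_number_distribution(d2, 400 + delta))
  # sigma = 0 degenerates to a point mass
  d0 <- size_distribution(400, sigma = 0)
  expect_equal(gaussian_number_distribution(d0, c(399, 400)), c(0, Inf))
})

test_that("inverse-CDF sampling reproduces the truncated mean", {
  d <- size_distribution(400, sigma_percent = 30, r_min = 60)
  set.seed(101)
  x <- sample_size_distribution(d, 1e5)
  expect_gte(min(x), 60)
  # truncation at 60 (2.8 sigma below) barely moves the mean
  expect_equal(mean(x), 400, tolerance = 2 / 400)
})

test_that("polydisperse intensity matches a dense Riemann sum over radii", {
  fx <- canonical_fixture()
  q <- c(1e-3, 5e-3, 0.02, 0.08, 0.2)
  got <- intensity_polydisperse(fx$profile, fx$dist, q)
  R <- seq(fx$dist$r_min, fx$dist$mean_radius + 6 * fx$dist$sigma,
           length.out = 2000)
  dR <- R[2] - R[1]
  ref <- numeric(length(q))
  for (k in seq_along(R)) {
    pk <- profile_at_radius(fx$profile, R[k])
    ref <- ref + gaussian_number_distribution(fx$dist, R[k]) *
      shell_amplitude(pk, q)^2 * dR
  }
  expect_lt(max(abs(got - ref) / ref), 1e-4)
})

test_that("polydispersity degenerates correctly and validates its configuration", {
  pv <- vesicle_profile(340, c(30, 30), c(1.5, -0.8))
  d0 <- size_distribution(400, sigma = 0)
  q <- 10^seq(-3, -0.6, length.out = 25)
  expect_equal(intensity_polydisperse(pv, d0, q),
               intensity_monodisperse(pv, q))
  # r_min below the wall thickness leaves no room for a water pool
  d_bad <- size_distribution(400, sigma_percent = 30, r_min = 50)
  expect_error(intensity_polydisperse(pv, d_bad, q),
               class = "luvsaxs_invalid_configuration")
  # forward intensity equals the D-weighted squared mass
  d <- size_distribution(400, sigma_percent = 25, r_min = 100)
  got0 <- intensity_polydisperse(pv, d, 0)
  R <- seq(100, 400 + 6 * 100, length.out = 4000)
  mass <- vapply(R, function(Ri) {
    pk <- profile_at_radius(pv, Ri)
    r <- pk$radii; r0 <- c(0, r[-3])
    sum(pk$contrasts * (sphere_volume(r) - sphere_volume(r0)))
  }, 1)
  ref0 <- sum(gaussian_number_distribution(d, R) * mass^2) * (R[2] - R[1])
  expect_equal(got0, ref0, tolerance = 1e-5)
})

test_that("fixed-thickness polydispersity varies the water pool, proportional mode scales all", {
  pv <- vesicle_profile(340, c(30, 30), c(1, -1))
  p_big <- profile_at_radius(pv, 500)
  expect_equal(shell_thicknesses(p_big), c(440, 30, 30))
  p_prop <- profile_at_radius(pv, 500, mode = "proportional")
  expect_equal(p_prop$radii, pv$radii * 1.25)
  expect_error(profile_at_radius(pv, 55),
               class = "luvsaxs_invalid_configuration")
})

test_that("closed-form Rg reproduces the solid-sphere and thin-shell limits", {
  expect_equal(analytic_rg(shell_profile(400, 1)), sqrt(3 / 5) * 400)
  thin <- vesicle_profile(400, 1e-4, 1, core_contrast = 0)
  expect_equal(analytic_rg(thin), 400, tolerance = 1e-6)
  # contrast-balanced profile has no net mass, hence no Rg
  balanced <- shell_profile(c(100, 100 * 2^(1 / 3)), c(1, -1))
  expect_error(analytic_rg(balanced), class = "luvsaxs_undefined_rg")
})
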