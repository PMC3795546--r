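# Real-space and Guinier analyses: p(r) by direct Fourier transform,
# bilayer-ripple extent, and radius of gyration from the Guinier regime.

#' Distance distribution function p(r) by direct Fourier transform
#'
#' \deqn{p(r) = \frac{r}{2\pi^2} \int_0^{\infty} q\, I(q) \sin(qr)\, dq,}
#' evaluated by trapezoidal quadrature on the curve's own q grid, truncated
#' at the data's \eqn{q_{\max}}. To suppress truncation ripples a cosine
#' taper over the last decade of q is applied by default; the untapered
#' transform is available with `taper = FALSE`.
#'
#' @param curve a [scattering_curve()]. The grid must be dense enough that
#'   \eqn{\Delta q \cdot \max(r) \le \pi} (otherwise an aliasing error is
#'   raised) and should extend low enough in q to capture the overall
#'   particle size.
#' @param r_grid real-space grid (\eqn{\mathrm{\AA}}); default
#'   `seq(0, 2000, by = 2)`, sized for vesicles up to \eqn{\sim}1000
#'   \eqn{\mathrm{\AA}} radius.
#' @param taper logical; apply the cosine taper window (default `TRUE`).
#' @param taper_decades width of the taper in decades of q (default 1).
#' @param extrapolate_low_q logical; extend the integral from the data's
#'   \eqn{q_{\min}} down to 0 with a Guinier-law extrapolation
#'   \eqn{I_0 e^{-q^2 R_g^2/3}} fitted to the lowest-q points (default
#'   `TRUE`). Without it, curves whose first point is not deep inside the
#'   Guinier regime produce low-frequency truncation artifacts at large r.
#' @return an object of class `distance_distribution`: a data frame with
#'   columns `r`, `p`, with attributes `peak_position` (abscissa of the
#'   global maximum, refined by 3-point parabolic interpolation) and
#'   `ripple_extent` (see [ripple_extent()]).
#' @export
distance_distribution <- function(curve, r_grid = seq(0, 2000, by = 2),
                                  taper = TRUE, taper_decades = 1,
                                  extrapolate_low_q = TRUE) {
  if (!inherits(curve, "scattering_curve"))
    abort_luvsaxs("curve must be a scattering_curve", "invalid_curve")
  q <- curve$q; I <- curve$I
  if (extrapolate_low_q && q[1] > 0) {
    # local Guinier-law fit to the first points of the curve; skipped when
    # the curve does not decay there (the artifact it guards against is
    # then absent anyway)
    n0 <- min(max(8L, findInterval(1.3 * q[1], q)), length(q))
    cf <- stats::lm.fit(cbind(1, q[seq_len(n0)]^2),
                        log(pmax(I[seq_len(n0)], .Machine$double.xmin)))$coefficients
    if (is.finite(cf[2]) && cf[2] < 0) {
      q_ext <- seq(0, q[1], length.out = 65L)[-65L]
      q <- c(q_ext, q)
      I <- c(exp(cf[1] + cf[2] * q_ext^2), I)
    }
  }
  if (max(diff(q)) * max(r_grid) > pi)
    abort_luvsaxs(sprintf(
      "q grid too sparse: max dq * max r = %.2f > pi; p(r) would alias",
      max(diff(q)) * max(r_grid)), "aliasing")
  w <- rep(1, length(q))
  if (taper) {
    lq <- log10(q)
    q_t <- max(lq) - taper_decades
    sel <- lq > q_t
    w[sel] <- 0.5 * (1 + cos(pi * (lq[sel] - q_t) / (max(lq) - q_t)))
  }
  wq <- trapz_weights(q) * q * I * w
  # p(r_j) = (r_j / 2 pi^2) * sum_i wq_i sin(q_i r_j)
  p <- drop(sin(outer(r_grid, q)) %*% wq) * r_grid / (2 * pi^2)
  dd <- structure(data.frame(r = r_grid, p = p),
                  class = c("distance_distribution", "data.frame"))
  attr(dd, "peak_position") <- pr_peak_position(dd)
  attr(dd, "ripple_extent") <- ripple_extent(dd)
  dd
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "distance_distribution: r in [%.0f, %.0f] A, peak at %.1f A, ripple extent %.1f A\n",
    min(x$r), max(x$r), attr(x, "peak_position"), attr(x, "ripple_extent")))
  invisible(x)
}

#' Abscissa of the global maximum of p(r)
#'
#' The discrete maximum refined by fitting a parabola through the three
#' surrounding points.
#'
#' @param dd a `distance_distribution`.
#' @return peak position (\eqn{\mathrm{\AA}}).
#' @export
pr_peak_position <- function(dd) {
  i <- which.max(dd$p)
  if (i == 1L || i == nrow(dd)) return(dd$r[i])
  r3 <- dd$r[(i - 1):(i + 1)]; p3 <- dd$p[(i - 1):(i + 1)]
  denom <- p3[1] - 2 * p3[2] + p3[3]
  if (denom >= 0) return(dd$r[i])   # flat or concave-up: keep grid point
  dd$r[i] + 0.5 * (p3[1] - p3[3]) / denom * (r3[2] - r3[1])
}

#' Extent of the sub-bilayer oscillation in p(r)
#'
#' The short-distance region of a vesicle p(r) oscillates in sign because
#' the hydrocarbon core is anticorrelated with the headgroup layers; protein
#' occlusion damps this ripple. The extent is the largest r below
#' `r_search` at which p(r) changes sign, provided the oscillation is real:
#' at least two sign changes between lobes whose amplitude exceeds
#' `min_amplitude_frac` of \eqn{\max |p|} (guarding against residual
#' truncation ripples). Returns 0 when no such oscillation is present (e.g.
#' a solid sphere, whose p(r) is nonnegative).
#'
#' @param dd a `distance_distribution`.
#' @param r_search upper end of the search window (\eqn{\mathrm{\AA}}).
#' @param min_amplitude_frac amplitude threshold as a fraction of the global
#'   \eqn{\max |p|}.
#' @return largest sign-change abscissa (\eqn{\mathrm{\AA}}), or 0.
#' @export
ripple_extent <- function(dd, r_search = 100, min_amplitude_frac = 0.005) {
  sel <- dd$r > 0 & dd$r <= r_search
  r <- dd$r[sel]; p <- dd$p[sel]
  thr <- min_amplitude_frac * max(abs(dd$p))
  s <- sign(p) * (abs(p) > thr)
  s_nz <- s[s != 0]
  if (length(s_nz) < 2L) return(0)
  flips <- which(diff(s_nz) != 0)
  if (length(flips) < 2L) return(0)
  # crossing abscissae: linear interpolation between the last same-signed
  # point and the first opposite-signed point
  idx_nz <- which(s != 0)
  cross_r <- numeric(0)
  for (k in seq_len(length(idx_nz) - 1)) {
    i1 <- idx_nz[k]; i2 <- idx_nz[k + 1]
    if (s[i1] != s[i2]) {
      # interpolate on the raw p between i1 and i2
      j <- i1 + which(diff(sign(p[i1:i2]) >= 0) != 0)[1] - 1
      if (is.na(j)) j <- i1
      cross_r <- c(cross_r,
                   r[j] - p[j] * (r[j + 1] - r[j]) / (p[j + 1] - p[j]))
    }
  }
  if (length(cross_r) < 2L) return(0)
  max(cross_r)
}

#' Reconstruct I(q) from a distance distribution
#'
#' Inverse of [distance_distribution()]:
#' \deqn{I(q) = 4\pi \int_0^{D_{\max}} p(r)\,\frac{\sin(qr)}{qr}\, dr.}
#' Mainly used to verify the transform round trip.
#'
#' @param dd a `distance_distribution`.
#' @param q q grid (\eqn{\mathrm{\AA}^{-1}}).
#' @return a [scattering_curve()].
#' @export
intensity_from_pr <- function(dd, q) {
  wr <- trapz_weights(dd$r) * dd$p
  x <- outer(q, dd$r)
  sinc <- ifelse(x < 1e-8, 1, sin(x) / x)
  scattering_curve(q, 4 * pi * drop(sinc %*% wr))
}

#' Guinier fit of the radius of gyration
#'
#' Weighted linear regression of \eqn{\ln I} on \eqn{q^2} over the largest
#' low-q window satisfying \eqn{q R_g \le} `qrg_max`, iterated to
#' self-consistency in \eqn{R_g}. The default bound 1.0 is chosen for large
#' vesicles, for which the classic \eqn{q R_g < 1.3} window already leaves
#' the linear regime. \eqn{R_g = \sqrt{-3 \times \mathrm{slope}}}.
#'
#' @param curve a [scattering_curve()]; when a `sigma` column is present the
#'   regression is weighted by \eqn{(I/\sigma)^2}.
#' @param qrg_max upper bound on \eqn{q R_g} (dimensionless).
#' @param min_points minimum number of points in the fit window.
#' @param max_iter iteration cap for the self-consistency loop.
#' @return an object of class `guinier_result`: list with `rg`, `i0`,
#'   `fit_q_range`, `rg_stderr`, `n_points`, `qrg_max_used`.
#' @export
guinier_fit <- function(curve, qrg_max = 1.0, min_points = 5, max_iter = 50) {
  if (!inherits(curve, "scattering_curve"))
    abort_luvsaxs("curve must be a scattering_curve", "invalid_curve")
  pos <- curve$I > 0
  q <- curve$q[pos]; I <- curve$I[pos]
  wts <- if ("sigma" %in% names(curve)) {
    s <- curve$sigma[pos]
    ifelse(s > 0, (I / s)^2, 0)
  } else rep(1, length(q))
  if (length(q) < min_points)
    abort_luvsaxs("too few positive-intensity points for a Guinier fit",
                  "no_guinier_regime")
  n_win <- min_points
  fit_window <- function(n) {
    idx <- seq_len(n)
    stats::lm.wfit(cbind(1, q[idx]^2), log(I[idx]), wts[idx])
  }
  fit <- fit_window(n_win)
  for (iter in seq_len(max_iter)) {
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) {
      # widen once in case the first points are flat; otherwise fail below
      if (n_win < length(q)) { n_win <- min(length(q), n_win * 2L); fit <- fit_window(n_win); next }
      abort_luvsaxs("intensity does not decay at low q; no Guinier regime",
                    "no_guinier_regime")
    }
    rg <- sqrt(-3 * slope)
    n_new <- max(min_points, findInterval(qrg_max / rg, q))
    if (n_new == n_win) break
    n_win <- n_new
    fit <- fit_window(n_win)
  }
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    abort_luvsaxs("intensity does not decay at low q; no Guinier regime",
                  "no_guinier_regime")
  rg <- sqrt(-3 * slope)
  # slope standard error from the weighted residuals
  res <- fit$residuals; X <- cbind(1, q[seq_len(n_win)]^2)
  dof <- max(1L, n_win - 2L)
  s2 <- sum(fit$weights * res^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  se_slope <- sqrt(s2 * xtx_inv[2, 2])
  structure(list(rg = unname(rg),
                 i0 = unname(exp(fit$coefficients[1])),
                 fit_q_range = c(q[1], q[n_win]),
                 rg_stderr = unname(3 * se_slope / (2 * rg)),
                 n_points = n_win,
                 qrg_max_used = unname(q[n_win] * rg)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.1f +/- %.1f A, I(0) = %.4g, %d points, q in [%.2g, %.2g] (q.Rg <= %.2f)\n",
    x$rg, x$rg_stderr, x$i0, x$n_points, x$fit_q_range[1], x$fit_q_range[2],
    x$qrg_max_used))
  invisible(x)
}
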