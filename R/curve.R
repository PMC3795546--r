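#' One-dimensional scattering curve
#'
#' A data frame with columns `q` (\eqn{\mathrm{\AA}^{-1}}, strictly
#' increasing, positive), `I` (intensity, arbitrary units) and optionally
#' `sigma` (uncertainty on `I`).
#'
#' @param q scattering vector magnitudes.
#' @param I intensities.
#' @param sigma optional uncertainties.
#' @param metadata optional named list (e.g. header comments) kept as an
#'   attribute.
#' @return an object of class `scattering_curve` (also a `data.frame`).
#' @export
scattering_curve <- function(q, I, sigma = NULL, metadata = list()) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I))
    abort_luvsaxs("q and I must have equal length", "invalid_curve")
  if (any(!is.finite(q)) || any(q <= 0) || any(diff(q) <= 0))
    abort_luvsaxs("q must be positive, finite and strictly increasing",
                  "invalid_curve")
  if (any(!is.finite(I)))
    abort_luvsaxs("intensities must be finite", "invalid_curve")
  df <- data.frame(q = q, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      abort_luvsaxs("sigma must match q in length", "invalid_curve")
    df$sigma <- sigma
  }
  structure(df, metadata = metadata,
            class = c("scattering_curve", "data.frame"))
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering_curve: %d points, q in [%.4g, %.4g] A^-1%s\n",
              nrow(x), min(x$q), max(x$q),
              if ("sigma" %in% names(x)) ", with uncertainties" else ""))
  invisible(x)
}

#' Default q grid for vesicle-scale simulations
#'
#' Hybrid grid: log-spaced below `q_linear_from` (resolving the Guinier
#' regime of particles several hundred \eqn{\mathrm{\AA}} across) and
#' uniform above it (keeping \eqn{\Delta q} small enough that the Fourier
#' transform to p(r) does not alias out to \eqn{r \approx 2000}
#' \eqn{\mathrm{\AA}}).
#'
#' @param q_min,q_max grid limits (\eqn{\mathrm{\AA}^{-1}}).
#' @param n total number of points (about 1/4 spent on the log section).
#' @param q_linear_from transition between the log and uniform sections.
#' @return numeric vector, strictly increasing.
#' @export
default_q_grid <- function(q_min = 3e-4, q_max = 0.3, n = 600,
                           q_linear_from = 3e-3) {
  if (q_linear_from <= q_min || q_linear_from >= q_max)
    return(exp(seq(log(q_min), log(q_max), length.out = n)))
  n_log <- max(2L, round(n / 4))
  lo <- exp(seq(log(q_min), log(q_linear_from), length.out = n_log + 1L))
  hi <- seq(q_linear_from, q_max, length.out = n - n_log)
  c(lo[-(n_log + 1L)], hi)
}

#' Model scattering curve of a polydisperse shell profile
#'
#' Thin wrapper building a [scattering_curve()] from
#' [intensity_polydisperse()].
#'
#' @inheritParams intensity_polydisperse
#' @param q q grid (default [default_q_grid()]).
#' @param ... passed to [intensity_polydisperse()].
#' @return a `scattering_curve`.
#' @export
model_curve <- function(profile, dist, q = default_q_grid(), ...) {
  scattering_curve(q, intensity_polydisperse(profile, dist, q, ...))
}
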