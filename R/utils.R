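# classed error conditions so callers can distinguish failure modes
abort_luvsaxs <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("luvsaxs_", class), "luvsaxs_error"),
                      call = call))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Sphere volume
#'
#' Volume of a sphere of radius \code{r}, \eqn{V(r) = (4/3)\pi r^3}.
#'
#' @param r radius (\eqn{\mathrm{\AA}}), vectorized.
#' @return volume (\eqn{\mathrm{\AA}^3}).
#' @export
sphere_volume <- function(r) (4 / 3) * pi * r^3

#' Normalized sphere form-factor amplitude
#'
#' \eqn{\Phi(x) = 3 j_1(x)/x = 3(\sin x - x\cos x)/x^3}, where \eqn{j_1} is
#' the spherical Bessel function of the first rank. \eqn{\Phi(0) = 1}.
#' A Taylor series is used below |x| = 1e-2 to avoid cancellation.
#'
#' @param x dimensionless argument (typically \eqn{qr}), vectorized.
#' @return \eqn{\Phi(x)}, dimensionless.
#' @export
sphere_form_amplitude <- function(x) {
  x2 <- x * x
  out <- 3 * (sin(x) - x * cos(x)) / (x2 * x)
  # series below |x| = 1e-2 avoids cancellation (and the 0/0 at x = 0):
  # 3 j1(x)/x = 1 - x^2/10 + x^4/280 - ...
  small <- which(x2 < 1e-4)
  if (length(small)) {
    xs2 <- x2[small]
    out[small] <- 1 - xs2 / 10 + xs2 * xs2 / 280
  }
  out
}

# Gauss-Legendre nodes/weights on [a, b]; memoised on order to avoid
# recomputing inside per-q loops.
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  g <- gl_cache[[key]]
  list(x = a + (b - a) * g$x, w = (b - a) * g$w)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}
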