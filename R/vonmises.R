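# von Mises circular distribution: sampling, moments, concentration
# estimation. Angles in radians internally; bearings at the interface are
# degrees clockwise from north.

log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

#' Draw von Mises deviates
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler. For very large
#' concentrations (`kappa > 5e5`) the distribution is numerically
#' indistinguishable from a wrapped normal with sd `1/sqrt(kappa)`, which is
#' used directly.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `> 0`.
#' @return Angles in radians in `(-pi, pi]` (plus `mu`).
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  stopifnot(kappa > 0)
  if (kappa > 5e5) {
    return((mu + stats::rnorm(n, 0, 1 / sqrt(kappa)) + pi) %% (2 * pi) - pi)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cq <- kappa * (r - f)
    ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    k <- sum(ok)
    if (k > 0L) {
      u3 <- stats::runif(k)
      theta <- sign(u3 - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

#' Circular standard deviation of a von Mises distribution
#'
#' Closed form `sqrt(-2 log(I1(kappa)/I0(kappa)))`.
#'
#' @param kappa Concentration.
#' @return Circular sd in radians.
#' @export
vm_circular_sd <- function(kappa) {
  A <- besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(A))
}

#' Rayleigh-style concentration estimate from angular residuals
#'
#' Maximum-likelihood estimate of the von Mises concentration via the mean
#' resultant length, using the standard piecewise inversion of
#' `A(kappa) = I1/I0` (Fisher 1993).
#'
#' @param theta Angles in radians.
#' @return Estimated concentration.
#' @export
vm_kappa_mle <- function(theta) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}
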