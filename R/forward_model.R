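#' @include tissue_models.R
NULL

# Complex refractive index sqrt(eps) on the branch with Re >= 0; for passive
# media (eps'' >= 0 in the eps' - i eps'' convention) the principal square
# root already satisfies this and gives a decaying transmission factor.
.refrIndex <- function(eps) {
  n <- sqrt(eps)
  flip <- Re(n) < 0
  n[flip] <- -n[flip]
  n
}

#' S-parameters of a sample-filled coaxial line section
#'
#' Exact TEM transmission-line model of a homogeneous sample of length `L`
#' filling the coaxial holder, referenced to the air-filled line impedance
#' (non-magnetic sample, so the normalized wave impedance is
#' \eqn{1/\sqrt{\epsilon}}):
#' \deqn{\Gamma = \frac{1-\sqrt{\epsilon}}{1+\sqrt{\epsilon}}, \quad
#'   T = e^{-i (\omega/c_0)\sqrt{\epsilon}\,L}}
#' \deqn{S_{11} = \frac{\Gamma(1-T^2)}{1-\Gamma^2T^2}, \quad
#'   S_{21} = \frac{T(1-\Gamma^2)}{1-\Gamma^2T^2}}
#' The device is reciprocal and symmetric (`s12 = s21`, `s22 = s11`), and a
#' lossless sample conserves energy: \eqn{|S_{11}|^2+|S_{21}|^2 = 1}.
#'
#' This is the physical forward model that the Nicolson-Ross extraction
#' ([extractPermittivity()]) inverts.
#'
#' @param eps A [PermittivitySpectrum-class] (passive: \eqn{\epsilon''} not
#'   below `-tol`).
#' @param L Sample length in metres.
#' @param tol Passivity tolerance on \eqn{\epsilon''}.
#' @return A [TwoPortSweep-class] on the spectrum's grid.
#' @examples
#' sp <- permittivitySpectrum(1e9, 4 + 0i)
#' sampleSParams(sp, 0.003)
#' @export
sampleSParams <- function(eps, L, tol = 1e-9) {
  stopifnot(is(eps, "PermittivitySpectrum"), L > 0)
  if (any(Im(eps@eps) > tol))
    stop("active medium: eps'' < 0 beyond tolerance")
  f <- eps@frequencies
  n <- .refrIndex(eps@eps)
  G <- (1 - n) / (1 + n)
  T <- exp(-1i * (2 * pi * f / .c0) * n * L)
  den <- 1 - G^2 * T^2
  twoPortSweep(f, s11 = G * (1 - T^2) / den, s21 = T * (1 - G^2) / den)
}

#' Synthesize a physically consistent calibration triple
#'
#' Builds the three sweeps a bench session produces, mutually consistent so
#' that [deembedSParams()] recovers the bare-sample sweep exactly:
#' \itemize{
#'   \item \emph{measurement}: [sampleSParams()] embedded in ideal air lines
#'     (each traversal of line \eqn{d_i} multiplies by \eqn{e^{-ikd_i}},
#'     \eqn{k = \omega/c_0});
#'   \item \emph{short-circuit}: reflection \eqn{-e^{-2ikd_i}} at each port
#'     (ideal short, reflection coefficient -1 at the sample face) and zero
#'     transmission;
#'   \item \emph{empty cell}: zero reflection, transmission
#'     \eqn{e^{-ik(d_1+L+d_2)}} across the full air-filled path.
#' }
#' The air lines are ideal (lossless, matched); the empty-cell reference
#' spans the full d1 + L + d2 path, the convention under which the
#' de-embedding phase identities are exact.
#'
#' @param eps A [PermittivitySpectrum-class] of the sample.
#' @param geom A [CellGeometry-class].
#' @param metadata Free-form list stored on the returned set.
#' @return A [MeasurementSet-class].
#' @examples
#' sp <- evaluatePermittivity(healthyLiverModel(), defaultFrequencyGrid())
#' ms <- synthesizeMeasurementSet(sp, cellGeometry())
#' @export
synthesizeMeasurementSet <- function(eps, geom = cellGeometry(),
                                     metadata = list()) {
  stopifnot(is(eps, "PermittivitySpectrum"), is(geom, "CellGeometry"))
  f <- eps@frequencies
  k <- 2 * pi * f / .c0
  bare <- sampleSParams(eps, geom@L)
  p1 <- exp(-1i * k * geom@d1)
  p2 <- exp(-1i * k * geom@d2)
  meas <- twoPortSweep(f,
    s11 = p1^2 * bare@s11, s21 = p1 * p2 * bare@s21,
    s12 = p1 * p2 * bare@s12, s22 = p2^2 * bare@s22)
  short <- twoPortSweep(f,
    s11 = -p1^2, s21 = rep(0 + 0i, length(f)),
    s12 = rep(0 + 0i, length(f)), s22 = -p2^2)
  thru <- exp(-1i * k * (geom@d1 + geom@L + geom@d2))
  empty <- twoPortSweep(f,
    s11 = rep(0 + 0i, length(f)), s21 = thru,
    s12 = thru, s22 = rep(0 + 0i, length(f)))
  measurementSet(meas, short, empty, geometry = geom, metadata = metadata)
}
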