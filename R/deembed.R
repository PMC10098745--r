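#' @include forward_model.R
NULL

#' De-embed a measured sweep to the sample reference planes
#'
#' Strips the air-line sections between the calibrated reference planes and
#' the sample faces, using the short-circuit sweep as the reflection
#' reference and the empty-cell sweep as the transmission reference.
#' Magnitudes and phases are corrected separately:
#' \deqn{|S_{ii}^{s}| = |S_{ii}^{m}| / |S_{ii}^{sc}|, \qquad
#'       |S_{ij}^{s}| = |S_{ij}^{m}| / |S_{ij}^{em}|}
#' \deqn{\varphi_{ii} = \varphi_{ii}^{m} - \varphi_{ii}^{sc} - \pi, \qquad
#'       \varphi_{ij} = \varphi_{ij}^{m} - \varphi_{ij}^{em} - kL}
#' with \eqn{k = \omega/c_0} and `L` from the set's geometry; superscripts
#' denote measurement, short-circuit, empty-cell and sample. The \eqn{-\pi}
#' removes the short's -1 reflection; the \eqn{-kL} compensates the sample
#' length included in the empty-cell transmission path. Both ports are
#' processed independently and output phases are wrapped to
#' \eqn{(-\pi, \pi]}.
#'
#' Normalizing reflection magnitude by \eqn{|S_{ii}^{sc}|} (rather than
#' assuming a unit-magnitude short) also compensates line loss on real
#' hardware; for the ideal synthetic references of
#' [synthesizeMeasurementSet()] the operation is the exact inverse of the
#' embedding.
#'
#' @param ms A [MeasurementSet-class].
#' @return A [TwoPortSweep-class] at the sample reference planes.
#' @examples
#' sp <- permittivitySpectrum(1e9, 4 + 0i)
#' ms <- synthesizeMeasurementSet(sp, cellGeometry())
#' deembedSParams(ms)
#' @export
deembedSParams <- function(ms) {
  stopifnot(is(ms, "MeasurementSet"))
  f <- ms@measurement@frequencies
  kL <- 2 * pi * f / .c0 * ms@geometry@L

  refl <- function(m, sc, port) {
    bad <- Mod(sc) == 0
    if (any(bad))
      stop(sprintf(
        "degenerate short-circuit reference (|S%s| = 0) at %g Hz",
        port, f[which(bad)[1]]))
    mag <- Mod(m) / Mod(sc)
    ph <- .wrapPhase(Arg(m) - Arg(sc) - pi)
    complex(modulus = mag, argument = ph)
  }
  tran <- function(m, em, port) {
    bad <- Mod(em) == 0
    if (any(bad))
      stop(sprintf(
        "degenerate empty-cell reference (|S%s| = 0) at %g Hz",
        port, f[which(bad)[1]]))
    mag <- Mod(m) / Mod(em)
    ph <- .wrapPhase(Arg(m) - Arg(em) - kL)
    complex(modulus = mag, argument = ph)
  }

  twoPortSweep(f,
    s11 = refl(ms@measurement@s11, ms@shortCircuit@s11, "11"),
    s21 = tran(ms@measurement@s21, ms@emptyCell@s21, "21"),
    s12 = tran(ms@measurement@s12, ms@emptyCell@s12, "12"),
    s22 = refl(ms@measurement@s22, ms@shortCircuit@s22, "22"))
}
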