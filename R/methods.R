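#' @include AllGenerics.R
NULL

## Constructors ---------------------------------------------------------------

#' Create a Debye/Cole-Cole tissue relaxation model
#'
#' @param epsInf High-frequency permittivity (>= 1).
#' @param deltaEps Relaxation strength(s), one per pole.
#' @param tau Relaxation time(s), seconds, one per pole.
#' @param sigmaS Static conductivity, S/m.
#' @param alpha Cole-Cole broadening exponent(s) in [0, 1); recycled to the
#'   number of poles. 0 (the default) gives a pure Debye pole.
#' @return A [DebyeModel-class].
#' @examples
#' m <- debyeModel(epsInf = 6, deltaEps = 36.14, tau = 10e-12, sigmaS = 0.5)
#' evaluatePermittivity(m, 1e9)
#' @export
debyeModel <- function(epsInf, deltaEps = numeric(), tau = numeric(),
                       sigmaS = 0, alpha = 0) {
  np <- length(deltaEps)
  if (np > 0L) alpha <- rep_len(alpha, np) else alpha <- numeric()
  new("DebyeModel", epsInf = as.numeric(epsInf),
      deltaEps = as.numeric(deltaEps), tau = as.numeric(tau),
      alpha = as.numeric(alpha), sigmaS = as.numeric(sigmaS))
}

#' Create a permittivity spectrum
#'
#' @param frequencies Strictly increasing frequencies, Hz.
#' @param eps Complex permittivity values (convention
#'   \eqn{\epsilon = \epsilon' - i\epsilon''}).
#' @param branch Integer log-branch per frequency (default 0).
#' @param flags Integer diagnostic flags per frequency (default 0).
#' @return A [PermittivitySpectrum-class].
#' @export
permittivitySpectrum <- function(frequencies, eps,
                                 branch = integer(length(frequencies)),
                                 flags = integer(length(frequencies))) {
  new("PermittivitySpectrum", frequencies = as.numeric(frequencies),
      eps = as.complex(eps), branch = as.integer(branch),
      flags = as.integer(flags))
}

#' Create a coaxial-cell geometry
#'
#' Defaults are the cell used throughout: a 3 mm sample holder flanked by
#' 96 mm air lines on each port, 50 ohm reference impedance.
#'
#' @param L Sample-holder length, metres.
#' @param d1,d2 Port-side air-line lengths, metres.
#' @param z0 Reference impedance, ohms.
#' @return A [CellGeometry-class].
#' @export
cellGeometry <- function(L = 0.003, d1 = 0.096, d2 = 0.096, z0 = 50) {
  new("CellGeometry", L = as.numeric(L), d1 = as.numeric(d1),
      d2 = as.numeric(d2), z0 = as.numeric(z0))
}

#' Create a two-port S-parameter sweep
#'
#' @param frequencies Strictly increasing frequencies, Hz.
#' @param s11,s21,s12,s22 Complex S-parameters per frequency. `s12` defaults
#'   to `s21` and `s22` to `s11` (reciprocal, symmetric device).
#' @return A [TwoPortSweep-class].
#' @export
twoPortSweep <- function(frequencies, s11, s21, s12 = s21, s22 = s11) {
  new("TwoPortSweep", frequencies = as.numeric(frequencies),
      s11 = as.complex(s11), s21 = as.complex(s21),
      s12 = as.complex(s12), s22 = as.complex(s22))
}

#' Create a measurement set (sample, short-circuit, empty-cell triple)
#'
#' @param measurement,shortCircuit,emptyCell [TwoPortSweep-class] objects on
#'   one common frequency grid.
#' @param geometry A [CellGeometry-class].
#' @param metadata Free-form list of specimen descriptors.
#' @return A [MeasurementSet-class].
#' @export
measurementSet <- function(measurement, shortCircuit, emptyCell,
                           geometry = cellGeometry(), metadata = list()) {
  new("MeasurementSet", measurement = measurement,
      shortCircuit = shortCircuit, emptyCell = emptyCell,
      geometry = geometry, metadata = metadata)
}

#' Create a cohort sample
#'
#' @param animalId Character id.
#' @param group `"control"` or `"HFS"`.
#' @param tissueModel A [DebyeModel-class].
#' @param biochemistry Named numeric vector of positive covariates.
#' @param measurementSet A [MeasurementSet-class].
#' @return A [CohortSample-class].
#' @export
cohortSample <- function(animalId, group, tissueModel, biochemistry,
                         measurementSet) {
  new("CohortSample", animalId = as.character(animalId),
      group = as.character(group), tissueModel = tissueModel,
      biochemistry = biochemistry, measurementSet = measurementSet)
}

## Accessors ------------------------------------------------------------------

#' @rdname frequencies
#' @export
setMethod("frequencies", "TwoPortSweep", function(x) x@frequencies)

#' @rdname frequencies
#' @export
setMethod("frequencies", "PermittivitySpectrum", function(x) x@frequencies)

#' @rdname frequencies
#' @export
setMethod("frequencies", "MeasurementSet",
          function(x) x@measurement@frequencies)

#' @rdname epsilonValues
#' @export
setMethod("epsilonValues", "PermittivitySpectrum", function(x) x@eps)

#' @rdname sParam
#' @export
setMethod("sParam", "TwoPortSweep", function(x, which) {
  which <- match.arg(which, c("s11", "s21", "s12", "s22"))
  slot(x, which)
})

#' @rdname MeasurementSet-class
#' @export
setMethod("measurementSweep", "MeasurementSet", function(x) x@measurement)

#' @rdname MeasurementSet-class
#' @export
setMethod("shortSweep", "MeasurementSet", function(x) x@shortCircuit)

#' @rdname MeasurementSet-class
#' @export
setMethod("emptySweep", "MeasurementSet", function(x) x@emptyCell)

#' @rdname MeasurementSet-class
#' @export
setMethod("cellGeom", "MeasurementSet", function(x) x@geometry)

#' Real part of a permittivity spectrum
#'
#' @param x A [PermittivitySpectrum-class].
#' @return Numeric vector \eqn{\epsilon'} per frequency.
#' @export
epsReal <- function(x) Re(epsilonValues(x))

#' Imaginary (loss) part of a permittivity spectrum
#'
#' Positive for lossy media under the convention
#' \eqn{\epsilon = \epsilon' - i\epsilon''}.
#'
#' @param x A [PermittivitySpectrum-class].
#' @return Numeric vector \eqn{\epsilon''} per frequency.
#' @export
epsImag <- function(x) -Im(epsilonValues(x))

#' Permittivity at one frequency
#'
#' @param x A [PermittivitySpectrum-class].
#' @param f Frequency in Hz; must lie on the spectrum's grid (to within
#'   `tol` relative).
#' @param tol Relative frequency-matching tolerance.
#' @return Single complex value.
#' @export
epsilonAt <- function(x, f, tol = 1e-9) {
  i <- which(abs(x@frequencies - f) <= tol * f)
  if (length(i) != 1L)
    stop("frequency ", f, " Hz is not on the spectrum grid")
  x@eps[i]
}

#' Passivity check for a two-port sweep
#'
#' A passive, reciprocal two-port satisfies
#' \eqn{|S_{11}|^2 + |S_{21}|^2 \le 1} at every frequency (and likewise from
#' port 2). Noise-perturbed sweeps may exceed the bound slightly.
#'
#' @param x A [TwoPortSweep-class].
#' @param tol Slack on the unit bound.
#' @return Logical: `TRUE` if both port sums respect the bound everywhere.
#' @export
isPassive <- function(x, tol = 1e-9) {
  p1 <- Mod(x@s11)^2 + Mod(x@s21)^2
  p2 <- Mod(x@s22)^2 + Mod(x@s12)^2
  all(p1 <= 1 + tol) && all(p2 <= 1 + tol)
}

## show methods ---------------------------------------------------------------

setMethod("show", "DebyeModel", function(object) {
  np <- length(object@deltaEps)
  cat(sprintf("DebyeModel: epsInf = %g, sigmaS = %g S/m, %d pole(s)\n",
              object@epsInf, object@sigmaS, np))
  if (np > 0)
    for (k in seq_len(np))
      cat(sprintf("  pole %d: deltaEps = %g, tau = %g s, alpha = %g\n",
                  k, object@deltaEps[k], object@tau[k], object@alpha[k]))
})

setMethod("show", "PermittivitySpectrum", function(object) {
  f <- object@frequencies
  cat(sprintf(
    "PermittivitySpectrum: %d points, %.4g-%.4g Hz\n", length(f),
    min(f), max(f)))
  cat(sprintf("  eps' range: [%.4g, %.4g]; eps'' range: [%.4g, %.4g]\n",
              min(Re(object@eps)), max(Re(object@eps)),
              min(-Im(object@eps)), max(-Im(object@eps))))
  if (any(object@flags != 0L))
    cat(sprintf("  %d flagged frequencies\n", sum(object@flags != 0L)))
})

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf(
    "CellGeometry: L = %g mm, d1 = %g mm, d2 = %g mm, z0 = %g ohm\n",
    1e3 * object@L, 1e3 * object@d1, 1e3 * object@d2, object@z0))
})

setMethod("show", "TwoPortSweep", function(object) {
  f <- object@frequencies
  cat(sprintf("TwoPortSweep: %d points, %.4g-%.4g Hz\n",
              length(f), min(f), max(f)))
})

setMethod("show", "MeasurementSet", function(object) {
  f <- object@measurement@frequencies
  cat(sprintf(
    "MeasurementSet: %d points, %.4g-%.4g Hz (measurement/short/empty)\n",
    length(f), min(f), max(f)))
  show(object@geometry)
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "CohortSample", function(object) {
  cat(sprintf("CohortSample %s [%s]\n", object@animalId, object@group))
  show(object@tissueModel)
})
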