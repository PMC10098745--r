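#' @include AllClasses.R
NULL

#' Frequency grid of a sweep or spectrum
#'
#' @param x A [TwoPortSweep-class], [PermittivitySpectrum-class] or
#'   [MeasurementSet-class].
#' @return Numeric vector of frequencies in Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Complex permittivity values of a spectrum
#'
#' Returns the stored complex values under the package convention
#' \eqn{\epsilon = \epsilon' - i\epsilon''}; use `Re()` for \eqn{\epsilon'}
#' and `-Im()` for \eqn{\epsilon''} (see [epsReal()], [epsImag()]).
#'
#' @param x A [PermittivitySpectrum-class].
#' @return Complex vector, one value per frequency.
#' @export
setGeneric("epsilonValues", function(x) standardGeneric("epsilonValues"))

#' One S-parameter of a two-port sweep
#'
#' @param x A [TwoPortSweep-class].
#' @param which One of `"s11"`, `"s21"`, `"s12"`, `"s22"`.
#' @return Complex vector, one value per frequency.
#' @export
setGeneric("sParam", function(x, which) standardGeneric("sParam"))

#' @rdname MeasurementSet-class
#' @param x A [MeasurementSet-class].
#' @export
setGeneric("measurementSweep", function(x) standardGeneric("measurementSweep"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("shortSweep", function(x) standardGeneric("shortSweep"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("emptySweep", function(x) standardGeneric("emptySweep"))

#' @rdname MeasurementSet-class
#' @export
setGeneric("cellGeom", function(x) standardGeneric("cellGeom"))
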