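#' @include coaxperm-package.R
NULL

## Central S4 data objects. Validity methods encode the physical invariants;
## user code goes through the constructors and accessors, never @ slots.

#' Debye/Cole-Cole dielectric relaxation model
#'
#' Parametric model of tissue complex relative permittivity
#' \deqn{\epsilon(\omega) = \epsilon_\infty +
#'   \sum_k \frac{\Delta\epsilon_k}{1 + (i\omega\tau_k)^{1-\alpha_k}}
#'   - i\,\frac{\sigma_s}{\omega \epsilon_0}}
#' with the package convention \eqn{\epsilon = \epsilon' - i\epsilon''},
#' \eqn{\epsilon'' \ge 0} for passive media. `alpha = 0` gives the pure Debye
#' pole; `0 < alpha < 1` gives Cole-Cole broadening.
#'
#' @slot epsInf High-frequency permittivity (dimensionless, >= 1).
#' @slot deltaEps Relaxation strengths, one per pole (dimensionless, >= 0).
#' @slot tau Relaxation times, one per pole (seconds, > 0).
#' @slot alpha Cole-Cole broadening exponents, one per pole (in [0, 1)).
#' @slot sigmaS Static ionic conductivity (S/m, >= 0).
#' @seealso [debyeModel()], [evaluatePermittivity()], [calibrateAnchor()]
#' @export
setClass("DebyeModel",
  representation(
    epsInf = "numeric",
    deltaEps = "numeric",
    tau = "numeric",
    alpha = "numeric",
    sigmaS = "numeric"
  )
)

setValidity("DebyeModel", function(object) {
  msg <- character()
  if (length(object@epsInf) != 1L || !is.finite(object@epsInf) ||
      object@epsInf < 1)
    msg <- c(msg, "epsInf must be a single finite number >= 1")
  np <- length(object@deltaEps)
  if (length(object@tau) != np || length(object@alpha) != np)
    msg <- c(msg, "deltaEps, tau and alpha must have one entry per pole")
  if (any(!is.finite(object@deltaEps)) || any(object@deltaEps < 0))
    msg <- c(msg, "deltaEps must be finite and >= 0")
  if (np > 0 && (any(!is.finite(object@tau)) || any(object@tau <= 0)))
    msg <- c(msg, "tau must be finite and > 0")
  if (np > 0 && (any(!is.finite(object@alpha)) ||
                 any(object@alpha < 0 | object@alpha >= 1)))
    msg <- c(msg, "alpha must lie in [0, 1)")
  if (length(object@sigmaS) != 1L || !is.finite(object@sigmaS) ||
      object@sigmaS < 0)
    msg <- c(msg, "sigmaS must be a single finite number >= 0")
  if (length(msg)) msg else TRUE
})

#' Complex relative permittivity spectrum
#'
#' Frequency-indexed complex relative permittivity, stored with the
#' convention \eqn{\epsilon = \epsilon' - i\epsilon''} (so the imaginary part
#' of the stored complex values is \eqn{-\epsilon''} and is non-positive for
#' passive media, up to numerical tolerance).
#'
#' @slot frequencies Strictly increasing frequencies, Hz.
#' @slot eps Complex relative permittivity, one value per frequency.
#' @slot branch Integer logarithm-branch index used per frequency (0 when the
#'   spectrum comes from a forward model rather than an extraction).
#' @slot flags Integer per-frequency diagnostic flags (0 = clean; 1 = the
#'   transmission factor was non-physical, `|T| >= 1`, for a nominally
#'   passive sample).
#' @seealso [permittivitySpectrum()], [extractPermittivity()]
#' @export
setClass("PermittivitySpectrum",
  representation(
    frequencies = "numeric",
    eps = "complex",
    branch = "integer",
    flags = "integer"
  )
)

setValidity("PermittivitySpectrum", function(object) {
  msg <- character()
  f <- object@frequencies
  if (length(f) < 1L || any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "frequencies must be finite and > 0")
  if (length(f) > 1L && any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@eps) != length(f))
    msg <- c(msg, "eps must have one value per frequency")
  if (any(!is.finite(Re(object@eps))))
    msg <- c(msg, "real part of eps must be finite")
  if (length(object@branch) != length(f) || length(object@flags) != length(f))
    msg <- c(msg, "branch and flags must have one value per frequency")
  if (length(msg)) msg else TRUE
})

#' Coaxial measuring-cell geometry
#'
#' @slot L Sample-holder length, metres (default 3 mm).
#' @slot d1,d2 Air-line lengths between the calibrated reference planes and
#'   the sample faces on ports 1 and 2, metres (default 96 mm each).
#' @slot z0 Reference impedance, ohms (default 50).
#' @seealso [cellGeometry()]
#' @export
setClass("CellGeometry",
  representation(L = "numeric", d1 = "numeric", d2 = "numeric",
                 z0 = "numeric")
)

setValidity("CellGeometry", function(object) {
  msg <- character()
  for (s in c("L", "d1", "d2", "z0")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("%s must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@L <= 0) msg <- c(msg, "L must be > 0")
    if (object@d1 < 0 || object@d2 < 0) msg <- c(msg, "d1, d2 must be >= 0")
    if (object@z0 <= 0) msg <- c(msg, "z0 must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Two-port S-parameter sweep
#'
#' Frequency-indexed complex 2x2 scattering matrices: `s11`/`s22` are port
#' reflection coefficients, `s21`/`s12` transmission coefficients. Passivity
#' (`|s11|^2 + |s21|^2 <= 1`) holds for noiseless synthetic sweeps and is
#' checked by [isPassive()], not by the class itself, since measured or
#' noise-perturbed data may exceed the bound slightly.
#'
#' @slot frequencies Strictly increasing frequencies, Hz.
#' @slot s11,s21,s12,s22 Complex S-parameters, one value per frequency.
#' @seealso [twoPortSweep()], [readTouchstone()], [sampleSParams()]
#' @export
setClass("TwoPortSweep",
  representation(
    frequencies = "numeric",
    s11 = "complex", s21 = "complex", s12 = "complex", s22 = "complex"
  )
)

setValidity("TwoPortSweep", function(object) {
  msg <- character()
  f <- object@frequencies
  if (length(f) < 1L || any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "frequencies must be finite and > 0")
  if (length(f) > 1L && any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  for (s in c("s11", "s21", "s12", "s22")) {
    v <- slot(object, s)
    if (length(v) != length(f))
      msg <- c(msg, sprintf("%s must have one value per frequency", s))
    else if (any(!is.finite(Re(v)) | !is.finite(Im(v))))
      msg <- c(msg, sprintf("%s must be finite", s))
  }
  if (length(msg)) msg else TRUE
})

#' Calibration triple for one specimen
#'
#' Bundles the three sweeps of the two-step cell-calibration protocol — the
#' sample measurement, the short-circuit reference and the empty-cell
#' reference — with the cell geometry and free-form specimen metadata.
#' [deembedSParams()] consumes this object.
#'
#' @slot measurement Sweep with the sample loaded in the holder.
#' @slot shortCircuit Sweep with the short-circuit standard in place of the
#'   holder (reflection references; `|s11|`, `|s22|` must be non-zero).
#' @slot emptyCell Sweep with the empty (air-filled) cell, spanning the full
#'   d1 + L + d2 path (transmission references; `|s21|`, `|s12|` must be
#'   non-zero).
#' @slot geometry [CellGeometry-class] of the cell.
#' @slot metadata Free-form list (specimen id, group label, minutes since
#'   excision, ...).
#' @seealso [measurementSet()], [synthesizeMeasurementSet()]
#' @export
setClass("MeasurementSet",
  representation(
    measurement = "TwoPortSweep",
    shortCircuit = "TwoPortSweep",
    emptyCell = "TwoPortSweep",
    geometry = "CellGeometry",
    metadata = "list"
  )
)

setValidity("MeasurementSet", function(object) {
  msg <- character()
  f <- object@measurement@frequencies
  if (!identical(f, object@shortCircuit@frequencies) ||
      !identical(f, object@emptyCell@frequencies))
    msg <- c(msg, "all three sweeps must share one frequency grid")
  if (any(Mod(object@shortCircuit@s11) == 0) ||
      any(Mod(object@shortCircuit@s22) == 0))
    msg <- c(msg, "short-circuit reflection references must be non-zero")
  if (any(Mod(object@emptyCell@s21) == 0) ||
      any(Mod(object@emptyCell@s12) == 0))
    msg <- c(msg, "empty-cell transmission references must be non-zero")
  if (length(msg)) msg else TRUE
})

#' One animal of a dielectric measurement cohort
#'
#' @slot animalId Character id.
#' @slot group Group label, `"control"` or `"HFS"`.
#' @slot tissueModel Per-animal [DebyeModel-class] (ground truth for
#'   synthetic cohorts).
#' @slot biochemistry Named numeric vector of covariates:
#'   `tg_liver_mmol_per_100g`, `glucose_liver_mg_per_mg_protein`,
#'   `tg_plasma_mmol_per_l`, `glucose_plasma_mmol_per_l`, `body_weight_g`,
#'   `liver_weight_g`. All strictly positive.
#' @slot measurementSet The animal's [MeasurementSet-class].
#' @seealso [generateCohort()]
#' @export
setClass("CohortSample",
  representation(
    animalId = "character",
    group = "character",
    tissueModel = "DebyeModel",
    biochemistry = "numeric",
    measurementSet = "MeasurementSet"
  )
)

setValidity("CohortSample", function(object) {
  msg <- character()
  if (length(object@group) != 1L || !object@group %in% c("control", "HFS"))
    msg <- c(msg, "group must be 'control' or 'HFS'")
  if (length(object@animalId) != 1L || !nzchar(object@animalId))
    msg <- c(msg, "animalId must be a non-empty string")
  b <- object@biochemistry
  if (length(b) && (is.null(names(b)) || any(!nzchar(names(b)))))
    msg <- c(msg, "biochemistry must be a named vector")
  if (length(b) && any(!is.finite(b) | b <= 0))
    msg <- c(msg, "biochemistry covariates must be finite and > 0")
  if (length(msg)) msg else TRUE
})
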