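#' @include methods.R
NULL

#' Evaluate a relaxation model on a frequency grid
#'
#' Computes
#' \deqn{\epsilon(\omega) = \epsilon_\infty +
#'   \sum_k \frac{\Delta\epsilon_k}{1 + (i\omega\tau_k)^{1-\alpha_k}}
#'   - i\,\frac{\sigma_s}{\omega\epsilon_0}}
#' under the \eqn{e^{+i\omega t}}, \eqn{\epsilon = \epsilon' - i\epsilon''}
#' convention, so every passive model yields \eqn{\epsilon'' \ge 0}.
#'
#' @param model A [DebyeModel-class].
#' @param frequencies Frequencies in Hz, strictly positive and increasing.
#' @return A [PermittivitySpectrum-class] on the same grid.
#' @examples
#' evaluatePermittivity(healthyLiverModel(), 1e9)
#' @export
evaluatePermittivity <- function(model, frequencies) {
  stopifnot(is(model, "DebyeModel"))
  f <- as.numeric(frequencies)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be finite and > 0")
  w <- 2 * pi * f
  eps <- complex(real = rep(model@epsInf, length(f)), imaginary = 0)
  for (k in seq_along(model@deltaEps)) {
    iwt <- (1i * w * model@tau[k])^(1 - model@alpha[k])
    eps <- eps + model@deltaEps[k] / (1 + iwt)
  }
  eps <- eps - 1i * model@sigmaS / (w * .eps0)
  permittivitySpectrum(f, eps)
}

#' Calibrate a single-pole Debye model to a printed permittivity anchor
#'
#' Fixes a one-pole Debye model (given \eqn{\epsilon_\infty} and \eqn{\tau})
#' so that it reproduces a target complex permittivity at one anchor
#' frequency. Both unknowns have closed forms: the relaxation strength from
#' the real-part equation,
#' \eqn{\Delta\epsilon = (\epsilon'_t - \epsilon_\infty)(1 + \omega^2\tau^2)},
#' then the static conductivity from the residual of the imaginary part,
#' \eqn{\sigma_s = (\epsilon''_t - \Delta\epsilon\,\omega\tau/(1+\omega^2\tau^2))\,\omega\epsilon_0}.
#'
#' @param epsInf High-frequency permittivity.
#' @param tau Relaxation time, seconds.
#' @param anchorF Anchor frequency, Hz.
#' @param targetEpsReal Target \eqn{\epsilon'} at the anchor (must exceed
#'   `epsInf`).
#' @param targetEpsImag Target \eqn{\epsilon''} at the anchor (>= 0; must be
#'   at least the relaxation loss implied by the real-part solution,
#'   otherwise no non-negative conductivity exists).
#' @return A [DebyeModel-class] reproducing both targets to 1e-9 relative.
#' @examples
#' calibrateAnchor(6, 10e-12, 1e9, 42, 11.249)
#' @export
calibrateAnchor <- function(epsInf, tau, anchorF, targetEpsReal,
                            targetEpsImag) {
  stopifnot(tau > 0, anchorF > 0, targetEpsImag >= 0)
  if (targetEpsReal <= epsInf)
    stop("infeasible anchor: targetEpsReal (", targetEpsReal,
         ") must exceed epsInf (", epsInf, ")")
  w <- 2 * pi * anchorF
  wt <- w * tau
  deltaEps <- (targetEpsReal - epsInf) * (1 + wt^2)
  relaxLoss <- deltaEps * wt / (1 + wt^2)
  sigmaS <- (targetEpsImag - relaxLoss) * w * .eps0
  if (sigmaS < 0)
    stop("infeasible anchor: relaxation loss alone (", signif(relaxLoss, 6),
         ") exceeds targetEpsImag (", targetEpsImag, ")")
  debyeModel(epsInf = epsInf, deltaEps = deltaEps, tau = tau,
             sigmaS = sigmaS)
}

#' Canonical healthy-liver tissue model
#'
#' Single-pole Debye model whose 1 GHz permittivity is
#' \eqn{\epsilon' = 42}, the group-mean value for healthy (control-diet)
#' mouse liver: \eqn{\epsilon_\infty = 6}, \eqn{\Delta\epsilon = 36.14},
#' \eqn{\tau = 10} ps, \eqn{\sigma_s = 0.500} S/m. \eqn{\epsilon_\infty}
#' and \eqn{\tau} are plausible placeholder values for liver in this band
#' (no relaxation parameters are published for this cohort); the other two
#' parameters follow from them via [calibrateAnchor()].
#'
#' @return A [DebyeModel-class].
#' @examples
#' epsilonAt(evaluatePermittivity(healthyLiverModel(),
#'                                defaultFrequencyGrid()), 1e9)
#' @export
healthyLiverModel <- function() {
  debyeModel(epsInf = 6, deltaEps = 36.14, tau = 10e-12, sigmaS = 0.500)
}

#' Canonical fatty-liver (HFS diet) tissue model
#'
#' Single-pole Debye model whose 1 GHz permittivity is
#' \eqn{\epsilon' = 31}, the group-mean value for fatty liver after a
#' high-fat/high-sugar (HFS) diet, with the loss part set to 65% of the
#' healthy model's (a 35% diminution of \eqn{\epsilon''}):
#' \eqn{\epsilon_\infty = 6}, \eqn{\Delta\epsilon = 25.10},
#' \eqn{\tau = 10} ps, \eqn{\sigma_s = 0.3194} S/m.
#'
#' @return A [DebyeModel-class].
#' @examples
#' epsilonAt(evaluatePermittivity(fattyLiverModel(),
#'                                defaultFrequencyGrid()), 1e9)
#' @export
fattyLiverModel <- function() {
  debyeModel(epsInf = 6, deltaEps = 25.10, tau = 10e-12, sigmaS = 0.3194)
}

#' Read or write tissue-model definitions as YAML config blocks
#'
#' A model serializes to a block with fields `name`, `eps_inf`, `poles`
#' (list of `delta_eps`/`tau_s`/`alpha`) and `sigma_s`; files round-trip
#' losslessly.
#'
#' @param model A [DebyeModel-class].
#' @param path File path.
#' @param name Model name recorded in the file.
#' @return `writeModelConfig()` returns `path` invisibly;
#'   `readModelConfig()` returns a named list with elements `name` and
#'   `model` (a [DebyeModel-class]).
#' @export
writeModelConfig <- function(model, path, name = "tissue_model") {
  stopifnot(is(model, "DebyeModel"))
  poles <- lapply(seq_along(model@deltaEps), function(k)
    list(delta_eps = model@deltaEps[k], tau_s = model@tau[k],
         alpha = model@alpha[k]))
  yaml::write_yaml(list(name = name, eps_inf = model@epsInf, poles = poles,
                        sigma_s = model@sigmaS), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (fld in c("name", "eps_inf", "sigma_s"))
    if (is.null(cfg[[fld]])) stop("model config missing field '", fld, "'")
  poles <- cfg$poles
  list(
    name = cfg$name,
    model = debyeModel(
      epsInf = cfg$eps_inf,
      deltaEps = vapply(poles, `[[`, numeric(1), "delta_eps"),
      tau = vapply(poles, `[[`, numeric(1), "tau_s"),
      sigmaS = cfg$sigma_s,
      alpha = if (length(poles))
        vapply(poles, `[[`, numeric(1), "alpha") else 0
    )
  )
}
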