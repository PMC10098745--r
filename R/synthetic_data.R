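#' @include cohort_stats.R
NULL

#' Configuration of a synthetic dielectric-measurement cohort
#'
#' Defines the study conditions the generator emulates: a 6-control vs
#' 10-HFS mouse cohort whose group-level real permittivity at 1 GHz is
#' 42 +/- 2 (control) and 31 +/- 3 (HFS), an HFS loss part at 65% of the
#' healthy one (a 35% diminution of \eqn{\epsilon''}), hepatic glucose
#' overlapping across groups in [0.4, 0.6] mg/mg protein, hepatic
#' triglycerides in [20, 40] mmol/100 g for HFS animals and below 20 for
#' controls, on a 100 MHz-2 GHz, 191-point sweep.
#'
#' @param nControl,nHfs Animals per group.
#' @param anchorF Anchor frequency for the permittivity targets, Hz.
#' @param meanControl,sdControl Mean and SD of \eqn{\epsilon'} at the anchor
#'   for the control group.
#' @param meanHfs,sdHfs Same for the HFS group.
#' @param imagRatioHfs Group-level ratio of HFS to healthy \eqn{\epsilon''}
#'   at the anchor (0.65 = a 35% diminution).
#' @param epsInf,tau Fixed Debye parameters shared by all per-animal models
#'   (see [healthyLiverModel()]).
#' @param magSd S-parameter multiplicative magnitude noise SD (fraction).
#' @param phaseSdDeg S-parameter additive phase noise SD, degrees.
#' @param fStart,fStop,nPoints Frequency grid specification, Hz.
#' @param geometry A [CellGeometry-class].
#' @param tgControlRange,tgHfsRange Hepatic triglyceride ranges per group,
#'   mmol/100 g.
#' @param glucoseControlRange,glucoseHfsRange Hepatic glucose ranges,
#'   mg/mg protein (overlapping by default).
#' @param seed Integer RNG seed, or `NULL` to use the caller's RNG stream.
#' @return Validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nControl = 6L, nHfs = 10L,
                         anchorF = 1e9,
                         meanControl = 42, sdControl = 2,
                         meanHfs = 31, sdHfs = 3,
                         imagRatioHfs = 0.65,
                         epsInf = 6, tau = 10e-12,
                         magSd = 0.005, phaseSdDeg = 0.5,
                         fStart = 100e6, fStop = 2e9, nPoints = 191L,
                         geometry = cellGeometry(),
                         tgControlRange = c(8, 19.5),
                         tgHfsRange = c(20, 40),
                         glucoseControlRange = c(0.40, 0.55),
                         glucoseHfsRange = c(0.45, 0.60),
                         seed = NULL) {
  cfg <- list(nControl = as.integer(nControl), nHfs = as.integer(nHfs),
              anchorF = anchorF, meanControl = meanControl,
              sdControl = sdControl, meanHfs = meanHfs, sdHfs = sdHfs,
              imagRatioHfs = imagRatioHfs, epsInf = epsInf, tau = tau,
              magSd = magSd, phaseSdDeg = phaseSdDeg,
              fStart = fStart, fStop = fStop, nPoints = as.integer(nPoints),
              geometry = geometry,
              tgControlRange = tgControlRange, tgHfsRange = tgHfsRange,
              glucoseControlRange = glucoseControlRange,
              glucoseHfsRange = glucoseHfsRange,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$nControl < 2L || cfg$nHfs < 2L) stop("need n >= 2 per group")
  if (cfg$sdControl < 0 || cfg$sdHfs < 0) stop("group sds must be >= 0")
  if (cfg$magSd < 0 || cfg$phaseSdDeg < 0) stop("noise sds must be >= 0")
  if (cfg$imagRatioHfs <= 0) stop("imagRatioHfs must be > 0")
  if (cfg$fStart <= 0 || cfg$fStop <= cfg$fStart || cfg$nPoints < 2L)
    stop("invalid frequency grid specification")
  class(cfg) <- "CohortConfig"
  cfg
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(
    "CohortConfig: %d control + %d HFS; eps'(%.3g Hz) %g+/-%g vs %g+/-%g\n",
    x$nControl, x$nHfs, x$anchorF, x$meanControl, x$sdControl,
    x$meanHfs, x$sdHfs))
  cat(sprintf("  grid %.3g-%.3g Hz (%d pts); noise mag %.3g, phase %.3g deg; seed %s\n",
              x$fStart, x$fStop, x$nPoints, x$magSd, x$phaseSdDeg,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Frequency grid of a cohort configuration
#'
#' @param config A [cohortConfig()] object.
#' @return Numeric vector of frequencies in Hz.
#' @export
configFrequencyGrid <- function(config) {
  seq(config$fStart, config$fStop, length.out = config$nPoints)
}

#' Add instrument noise to a sweep
#'
#' Multiplicative magnitude perturbation (`mag * (1 + N(0, magSd))`) and
#' additive phase perturbation (`N(0, phaseSdDeg)` degrees), independent per
#' frequency and per S-parameter. Zero sds return the sweep unchanged
#' without consuming RNG state.
#'
#' @param sweep A [TwoPortSweep-class].
#' @param magSd Magnitude noise SD as a fraction.
#' @param phaseSdDeg Phase noise SD in degrees.
#' @param seed Optional integer seed (caller's RNG state is restored); with
#'   `NULL` the current RNG stream is used.
#' @return A [TwoPortSweep-class].
#' @export
addInstrumentNoise <- function(sweep, magSd, phaseSdDeg, seed = NULL) {
  stopifnot(is(sweep, "TwoPortSweep"), magSd >= 0, phaseSdDeg >= 0)
  if (magSd == 0 && phaseSdDeg == 0) return(sweep)
  .withSeed(seed, {
    nf <- length(sweep@frequencies)
    perturb <- function(s) {
      mag <- Mod(s) * (1 + rnorm(nf, sd = magSd))
      ph <- Arg(s) + rnorm(nf, sd = phaseSdDeg * pi / 180)
      complex(modulus = pmax(mag, 0), argument = ph)
    }
    twoPortSweep(sweep@frequencies,
                 s11 = perturb(sweep@s11), s21 = perturb(sweep@s21),
                 s12 = perturb(sweep@s12), s22 = perturb(sweep@s22))
  })
}

# Draw one truncated-normal anchor with bounded retries.
.drawAnchor <- function(mean, sd, lower, maxTries = 100L) {
  for (i in seq_len(maxTries)) {
    x <- rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("could not draw a feasible permittivity anchor (", maxTries,
       " retries); check group mean/sd against epsInf")
}

.clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Generate a synthetic measurement cohort
#'
#' Produces one complete cohort of [CohortSample-class] objects. Per animal:
#' \enumerate{
#'   \item draw the target \eqn{\epsilon'} at the anchor frequency from the
#'     group's normal distribution (truncated above `epsInf + 1`, bounded
#'     retries);
#'   \item set the \eqn{\epsilon''} target by scaling the healthy reference
#'     loss in proportion to the drawn \eqn{\epsilon'}, times the group loss
#'     ratio (1 for control, `imagRatioHfs` for HFS), and calibrate a
#'     per-animal single-pole Debye model with [calibrateAnchor()];
#'   \item synthesize the sample/short/empty measurement triple with
#'     [synthesizeMeasurementSet()] and perturb all three sweeps with
#'     [addInstrumentNoise()];
#'   \item draw biochemistry covariates, with hepatic triglycerides linear
#'     in the drawn \eqn{\epsilon'} (negative slope) then clipped into the
#'     group's range — so permittivity and hepatic TG are negatively
#'     associated across the pooled cohort by construction.
#' }
#' Given a seed the output is fully reproducible.
#'
#' @param config A [cohortConfig()].
#' @return List of [CohortSample-class] (controls first).
#' @examples
#' cohort <- generateCohort(cohortConfig(seed = 1))
#' table(vapply(cohort, function(s) s@group, character(1)))
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  f <- configFrequencyGrid(config)
  # healthy reference loss at the anchor, from the group-mean control model
  refModel <- calibrateAnchor(config$epsInf, config$tau, config$anchorF,
                              config$meanControl,
                              epsImag(evaluatePermittivity(
                                healthyLiverModel(), config$anchorF)))
  refImag <- epsImag(evaluatePermittivity(refModel, config$anchorF))

  .withSeed(config$seed, {
    groups <- c(rep("control", config$nControl), rep("HFS", config$nHfs))
    lapply(seq_along(groups), function(i) {
      grp <- groups[i]
      gm <- if (grp == "control") config$meanControl else config$meanHfs
      gs <- if (grp == "control") config$sdControl else config$sdHfs
      ratio <- if (grp == "control") 1 else config$imagRatioHfs
      epsDraw <- .drawAnchor(gm, gs, config$epsInf + 1)
      # per-animal loss scales with its own anchor relative to the group
      # mean, so the group-mean eps'' ratio equals the configured ratio
      imagTarget <- refImag * (epsDraw / gm) * ratio
      model <- calibrateAnchor(config$epsInf, config$tau, config$anchorF,
                               epsDraw, imagTarget)
      ms <- synthesizeMeasurementSet(
        evaluatePermittivity(model, f), config$geometry,
        metadata = list(specimen_id = sprintf("animal_%02d", i),
                        group = grp, minutes_since_excision = 4))
      if (config$magSd > 0 || config$phaseSdDeg > 0)
        ms <- measurementSet(
          addInstrumentNoise(ms@measurement, config$magSd,
                             config$phaseSdDeg),
          addInstrumentNoise(ms@shortCircuit, config$magSd,
                             config$phaseSdDeg),
          addInstrumentNoise(ms@emptyCell, config$magSd,
                             config$phaseSdDeg),
          geometry = ms@geometry, metadata = ms@metadata)
      tgRange <- if (grp == "control") config$tgControlRange
                 else config$tgHfsRange
      gluRange <- if (grp == "control") config$glucoseControlRange
                  else config$glucoseHfsRange
      bio <- c(
        # linear-in-eps' mean with additive noise, clipped into the group
        # range: keeps the pooled TG-permittivity association negative
        tg_liver_mmol_per_100g =
          .clip(66 - 1.2 * epsDraw + rnorm(1, sd = 1.5), tgRange),
        glucose_liver_mg_per_mg_protein = runif(1, gluRange[1], gluRange[2]),
        # plasma and weight covariates: plausible placeholder distributions
        tg_plasma_mmol_per_l = max(rnorm(1, 1.0, 0.2), 0.2),
        glucose_plasma_mmol_per_l =
          max(rnorm(1, if (grp == "control") 8 else 11, 1), 3),
        body_weight_g =
          max(rnorm(1, if (grp == "control") 28 else 42,
                    if (grp == "control") 2 else 4), 15),
        liver_weight_g =
          max(rnorm(1, if (grp == "control") 1.3 else 2.2,
                    if (grp == "control") 0.15 else 0.3), 0.5))
      cohortSample(sprintf("animal_%02d", i), grp, model, bio, ms)
    })
  })
}
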