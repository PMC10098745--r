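#' @include io_csv.R
NULL

.cfgScalarFields <- c("nControl", "nHfs", "anchorF", "meanControl",
                      "sdControl", "meanHfs", "sdHfs", "imagRatioHfs",
                      "epsInf", "tau", "magSd", "phaseSdDeg",
                      "fStart", "fStop", "nPoints", "seed")
.cfgRangeFields <- c("tgControlRange", "tgHfsRange",
                     "glucoseControlRange", "glucoseHfsRange")

#' Read or write a cohort configuration as YAML
#'
#' Serializes every [cohortConfig()] field (geometry as a `geometry` block
#' with `L_m`, `d1_m`, `d2_m`, `z0_ohm`). Reading validates through
#' [cohortConfig()] and rejects unknown keys, so a config file round-trips
#' losslessly or fails loudly.
#'
#' @param config A [cohortConfig()].
#' @param path File path.
#' @return `writeCohortConfigYaml()` returns `path` invisibly;
#'   `readCohortConfigYaml()` returns a validated [cohortConfig()].
#' @export
writeCohortConfigYaml <- function(config, path) {
  stopifnot(inherits(config, "CohortConfig"))
  out <- config[.cfgScalarFields]
  out <- out[!vapply(out, is.null, logical(1))]
  for (fld in .cfgRangeFields) out[[fld]] <- config[[fld]]
  g <- config$geometry
  out$geometry <- list(L_m = g@L, d1_m = g@d1, d2_m = g@d2, z0_ohm = g@z0)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname writeCohortConfigYaml
#' @export
readCohortConfigYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(.cfgScalarFields, .cfgRangeFields, "geometry")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- cfg[setdiff(names(cfg), "geometry")]
  for (fld in .cfgRangeFields)
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    bad <- setdiff(names(g), c("L_m", "d1_m", "d2_m", "z0_ohm"))
    if (length(bad))
      stop("unknown geometry key(s): ", paste(bad, collapse = ", "))
    args$geometry <- cellGeometry(
      L = if (is.null(g$L_m)) 0.003 else g$L_m,
      d1 = if (is.null(g$d1_m)) 0.096 else g$d1_m,
      d2 = if (is.null(g$d2_m)) 0.096 else g$d2_m,
      z0 = if (is.null(g$z0_ohm)) 50 else g$z0_ohm)
  }
  do.call(cohortConfig, args)
}
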