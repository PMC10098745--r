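#' @include nrw.R
NULL

#' Per-group spectral summary with repeatability band
#'
#' Summarizes a group's permittivity spectra per frequency: mean, sample
#' standard deviation (n - 1 denominator), standard error of the mean
#' (sem = sd / sqrt(n)) for both \eqn{\epsilon'} and \eqn{\epsilon''}, plus
#' a fixed fractional repeatability band of +/- 10% around the group mean
#' (`band_lo = 0.9 * mean`, `band_hi = 1.1 * mean`). The band mirrors the
#' dotted repeatability envelope drawn around group-mean tissue spectra; it
#' is not a statistical confidence interval.
#'
#' @param spectra List of [PermittivitySpectrum-class] objects on one common
#'   frequency grid (at least 2).
#' @param group Group label stored on the summary.
#' @param bandFraction Half-width of the repeatability band as a fraction of
#'   the mean (default 0.10).
#' @return A `GroupSpectraSummary`: a list with `group`, `n`, `frequencies`
#'   and a data frame `table` with columns `frequency_hz` and, for each of
#'   `real`/`imag`: `mean_*`, `sd_*`, `sem_*`, `band_lo_*`, `band_hi_*`.
#' @examples
#' sp <- replicate(3, evaluatePermittivity(healthyLiverModel(), c(1e9, 2e9)))
#' summarizeGroupSpectra(sp, "control")
#' @export
summarizeGroupSpectra <- function(spectra, group, bandFraction = 0.10) {
  if (length(spectra) < 2L)
    stop("need at least 2 spectra to summarize a group")
  f <- frequencies(spectra[[1]])
  for (s in spectra)
    if (!identical(frequencies(s), f))
      stop("spectra are not on a common frequency grid")
  n <- length(spectra)
  re <- vapply(spectra, epsReal, numeric(length(f)))
  im <- vapply(spectra, epsImag, numeric(length(f)))
  if (length(f) == 1L) { re <- matrix(re, nrow = 1); im <- matrix(im, nrow = 1) }
  part <- function(m, nm) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    out <- data.frame(mu, sdv, sdv / sqrt(n),
                      (1 - bandFraction) * mu, (1 + bandFraction) * mu)
    names(out) <- paste0(c("mean_", "sd_", "sem_", "band_lo_", "band_hi_"),
                         nm)
    out
  }
  structure(
    list(group = group, n = n, frequencies = f,
         table = cbind(data.frame(frequency_hz = f),
                       part(re, "real"), part(im, "imag"))),
    class = "GroupSpectraSummary")
}

#' @export
print.GroupSpectraSummary <- function(x, ...) {
  cat(sprintf("GroupSpectraSummary '%s': n = %d, %d frequencies\n",
              x$group, x$n, length(x$frequencies)))
  i <- which.min(abs(x$frequencies - 1e9))
  cat(sprintf("  near %.3g Hz: eps' = %.2f +/- %.2f (sem), eps'' = %.2f +/- %.2f\n",
              x$frequencies[i], x$table$mean_real[i], x$table$sem_real[i],
              x$table$mean_imag[i], x$table$sem_imag[i]))
  invisible(x)
}

#' Percent diminution of permittivity between two group summaries
#'
#' Signed percent drop of the second group's mean relative to the first,
#' \eqn{100\,(\bar\epsilon_{ctrl} - \bar\epsilon_{hfs})/\bar\epsilon_{ctrl}},
#' at one frequency; positive when the second (fatty) group is lower.
#'
#' @param control,hfs `GroupSpectraSummary` objects on one grid.
#' @param f Frequency in Hz, on the common grid.
#' @param part `"real"` or `"imag"`.
#' @return Signed percent (single numeric).
#' @export
percentDiminution <- function(control, hfs, f, part = c("real", "imag")) {
  part <- match.arg(part)
  if (!identical(control$frequencies, hfs$frequencies))
    stop("summaries are not on a common frequency grid")
  i <- which(abs(control$frequencies - f) <= 1e-9 * f)
  if (length(i) != 1L) stop("frequency ", f, " Hz is not on the grid")
  col <- paste0("mean_", part)
  mc <- control$table[[col]][i]
  mh <- hfs$table[[col]][i]
  if (mc == 0) stop("control mean is zero at ", f, " Hz")
  100 * (mc - mh) / mc
}

.statResult <- function(method, statistic, p, n) {
  list(method = method, statistic = unname(statistic),
       p_value = unname(p), n_per_group = n)
}

#' Normality check and unpaired two-group comparison
#'
#' The two-group analysis chain: Shapiro-Wilk normality test on each group,
#' then a two-tailed unpaired t-test. "Unpaired t-test" is interpreted as
#' Student's pooled-variance test (the default reading of that phrase in
#' GraphPad Prism); set `welch = TRUE` for the unequal-variance form.
#'
#' @param a,b Numeric vectors, one per group (n >= 3 each, for the
#'   normality test).
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student form.
#' @return List with elements `normality_a`, `normality_b` (Shapiro-Wilk W
#'   and p) and `t_test` (t statistic, p, df in `statistic`/`p_value`/`df`),
#'   each carrying `n_per_group`.
#' @examples
#' compareGroups(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
compareGroups <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("need n >= 3 per group")
  # Shapiro-Wilk is undefined on constant data; report NA rather than fail
  swSafe <- function(x) {
    if (sd(x) == 0)
      return(.statResult("shapiro-wilk", NA_real_, NA_real_, length(x)))
    sw <- shapiro.test(x)
    .statResult("shapiro-wilk", sw$statistic, sw$p.value, length(x))
  }
  sw_a <- swSafe(a)
  sw_b <- swSafe(b)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- .statResult("t-unpaired-two-tailed", 0, 1,
                        c(length(a), length(b)))
      tt$df <- length(a) + length(b) - 2
    } else {
      stop("degenerate variance: both groups constant with unequal means")
    }
  } else {
    ht <- t.test(a, b, var.equal = !welch)
    tt <- .statResult("t-unpaired-two-tailed", ht$statistic, ht$p.value,
                      c(length(a), length(b)))
    tt$df <- unname(ht$parameter)
  }
  list(normality_a = sw_a, normality_b = sw_b, t_test = tt)
}

#' Run the de-embed + extraction pipeline over a cohort
#'
#' @param cohort List of [CohortSample-class] objects.
#' @param opts [nrwOptions()] passed to the extraction.
#' @return Named list (by animal id) of [PermittivitySpectrum-class].
#' @export
extractCohortSpectra <- function(cohort, opts = nrwOptions()) {
  out <- lapply(cohort, function(s) {
    ms <- s@measurementSet
    extractPermittivity(deembedSParams(ms), ms@geometry@L, opts)
  })
  names(out) <- vapply(cohort, function(s) s@animalId, character(1))
  out
}

#' Permittivity-vs-biochemistry association at one frequency
#'
#' Builds the per-animal table relating extracted \eqn{\epsilon'(f)} to the
#' hepatic covariates (triglycerides, glucose) and reports the pooled
#' Pearson correlation of \eqn{\epsilon'} with each. A constant covariate
#' gives an undefined correlation, reported as `NA`.
#'
#' @param cohort List of [CohortSample-class] objects.
#' @param f Frequency in Hz (on the common grid).
#' @param spectra Optional named list of extracted
#'   [PermittivitySpectrum-class] (ids matching the cohort); computed with
#'   [extractCohortSpectra()] when omitted.
#' @return List with `table` (data frame: `animal_id`, `group`, `eps_real`,
#'   `tg_liver_mmol_per_100g`, `glucose_liver_mg_per_mg_protein`) and
#'   `pearson` (named numeric: `tg_liver`, `glucose_liver`).
#' @export
associationAtFrequency <- function(cohort, f, spectra = NULL) {
  if (is.null(spectra)) spectra <- extractCohortSpectra(cohort)
  tab <- do.call(rbind, lapply(cohort, function(s) {
    sp <- spectra[[s@animalId]]
    if (is.null(sp)) stop("no extracted spectrum for ", s@animalId)
    data.frame(
      animal_id = s@animalId, group = s@group,
      eps_real = Re(epsilonAt(sp, f)),
      tg_liver_mmol_per_100g = s@biochemistry[["tg_liver_mmol_per_100g"]],
      glucose_liver_mg_per_mg_protein =
        s@biochemistry[["glucose_liver_mg_per_mg_protein"]])
  }))
  rownames(tab) <- NULL
  safeCor <- function(x) {
    if (sd(x) == 0 || sd(tab$eps_real) == 0) NA_real_
    else cor(tab$eps_real, x)
  }
  list(table = tab,
       pearson = c(tg_liver = safeCor(tab$tg_liver_mmol_per_100g),
                   glucose_liver =
                     safeCor(tab$glucose_liver_mg_per_mg_protein)))
}
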