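#' @include io_touchstone.R
NULL

#' Read or write a permittivity spectrum as CSV
#'
#' The interchange columns are `frequency_hz`, `eps_real`, `eps_imag`
#' (\eqn{\epsilon''}, positive for loss), `branch_n`, `flags`.
#'
#' @param x A [PermittivitySpectrum-class].
#' @param path File path.
#' @return `writeSpectrumCsv()` returns `path` invisibly;
#'   `readSpectrumCsv()` returns a [PermittivitySpectrum-class].
#' @export
writeSpectrumCsv <- function(x, path) {
  stopifnot(is(x, "PermittivitySpectrum"))
  write.csv(data.frame(frequency_hz = x@frequencies,
                       eps_real = Re(x@eps), eps_imag = -Im(x@eps),
                       branch_n = x@branch, flags = x@flags),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumCsv
#' @export
readSpectrumCsv <- function(path) {
  d <- read.csv(path)
  need <- c("frequency_hz", "eps_real", "eps_imag")
  if (!all(need %in% names(d)))
    stop("spectrum CSV must have columns ", paste(need, collapse = ", "))
  permittivitySpectrum(
    d$frequency_hz,
    complex(real = d$eps_real, imaginary = -d$eps_imag),
    branch = if ("branch_n" %in% names(d)) d$branch_n
             else integer(nrow(d)),
    flags = if ("flags" %in% names(d)) d$flags else integer(nrow(d)))
}

#' Write cohort metadata as CSV
#'
#' One row per animal: `animal_id`, `group` and the biochemistry covariates.
#'
#' @param cohort List of [CohortSample-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  tab <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(animal_id = s@animalId, group = s@group,
               as.list(s@biochemistry), check.names = FALSE)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic cohort to disk
#'
#' Writes, under `dir`: one `<animal_id>_{measurement,short,empty}.s2p`
#' trio per animal plus `cohort.csv` with the metadata. Given the same
#' [cohortConfig()] (including seed) the files are byte-identical across
#' runs.
#'
#' @param cohort List of [CohortSample-class] from [generateCohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
saveCohortFixtures <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort)
    writeMeasurementSetS2p(s@measurementSet, dir, prefix = s@animalId)
  writeCohortCsv(cohort, file.path(dir, "cohort.csv"))
  invisible(dir)
}

#' Group analysis of a directory of extracted spectra
#'
#' Consumes per-animal spectrum CSVs (named `<animal_id>.csv`, the
#' [writeSpectrumCsv()] layout) plus a cohort metadata CSV with columns
#' `animal_id`, `group`, `tg_liver_mmol_per_100g`,
#' `glucose_liver_mg_per_mg_protein`, and produces the group-level results:
#' per-group spectral summaries with the +/-10% repeatability band, percent
#' diminutions of \eqn{\epsilon'} and \eqn{\epsilon''} at `f0`, the
#' Shapiro-Wilk + unpaired t-test chain on \eqn{\epsilon'(f_0)}, and the
#' permittivity-vs-biochemistry Pearson correlations.
#'
#' @param spectraDir Directory of `<animal_id>.csv` spectrum files.
#' @param metadataCsv Path to the cohort metadata CSV.
#' @param outDir Optional output directory; when given, writes
#'   `group_summary.csv` (both groups, long format) and
#'   `test_results.json`.
#' @param f0 Analysis frequency, Hz (default 1 GHz).
#' @return List with `summaries` (per group), `diminution_real`,
#'   `diminution_imag`, `tests` (from [compareGroups()]), `association`
#'   (table + Pearson correlations), invisibly when `outDir` is given.
#' @export
analyzeCohortDir <- function(spectraDir, metadataCsv, outDir = NULL,
                             f0 = 1e9) {
  meta <- read.csv(metadataCsv)
  need <- c("animal_id", "group")
  if (!all(need %in% names(meta)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "))
  spectra <- lapply(meta$animal_id, function(id) {
    p <- file.path(spectraDir, paste0(id, ".csv"))
    if (!file.exists(p)) stop("missing spectrum file ", p)
    readSpectrumCsv(p)
  })
  names(spectra) <- meta$animal_id

  byGroup <- split(seq_len(nrow(meta)), meta$group)
  if (!setequal(names(byGroup), c("control", "HFS")))
    stop("metadata groups must be exactly 'control' and 'HFS'")
  summaries <- lapply(names(byGroup), function(g)
    summarizeGroupSpectra(spectra[byGroup[[g]]], g))
  names(summaries) <- names(byGroup)

  epsAt <- vapply(spectra, function(s) Re(epsilonAt(s, f0)), numeric(1))
  tests <- compareGroups(epsAt[byGroup$control], epsAt[byGroup$HFS])

  dimRe <- percentDiminution(summaries$control, summaries$HFS, f0, "real")
  dimIm <- percentDiminution(summaries$control, summaries$HFS, f0, "imag")

  assoc <- NULL
  if (all(c("tg_liver_mmol_per_100g", "glucose_liver_mg_per_mg_protein")
          %in% names(meta))) {
    tab <- data.frame(
      animal_id = meta$animal_id, group = meta$group, eps_real = epsAt,
      tg_liver_mmol_per_100g = meta$tg_liver_mmol_per_100g,
      glucose_liver_mg_per_mg_protein =
        meta$glucose_liver_mg_per_mg_protein)
    rownames(tab) <- NULL
    sc <- function(x) if (sd(x) == 0) NA_real_ else cor(epsAt, x)
    assoc <- list(table = tab,
                  pearson = c(tg_liver = sc(tab$tg_liver_mmol_per_100g),
                              glucose_liver =
                                sc(tab$glucose_liver_mg_per_mg_protein)))
  }

  res <- list(summaries = summaries, diminution_real = dimRe,
              diminution_imag = dimIm, tests = tests, association = assoc,
              f0 = f0)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    long <- do.call(rbind, lapply(summaries, function(s)
      cbind(group = s$group, n = s$n, s$table)))
    write.csv(long, file.path(outDir, "group_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(f0_hz = f0,
           diminution_real_percent = dimRe,
           diminution_imag_percent = dimIm,
           shapiro_control = res$tests$normality_a,
           shapiro_hfs = res$tests$normality_b,
           t_test = res$tests$t_test,
           pearson = as.list(if (is.null(assoc)) NULL else assoc$pearson)),
      file.path(outDir, "test_results.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(res))
  }
  res
}
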