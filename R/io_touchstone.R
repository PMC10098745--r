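#' @include synthetic_data.R
NULL

.tsUnits <- c(hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)

#' Read a two-port Touchstone (.s2p) file
#'
#' Parses Touchstone v1 two-port files: `!` comment lines, one `#` option
#' line (frequency unit Hz/kHz/MHz/GHz; parameter type `S`; format `RI`,
#' `MA` (magnitude/angle-degrees) or `DB` (dB magnitude/angle-degrees);
#' reference resistance), and data rows in the standard 2-port column order
#' `f  S11  S21  S12  S22` (two numbers per parameter). Frequencies are
#' normalized to Hz and values to complex real/imaginary internally. A v2
#' file (detected by a `[Version]` keyword) is accepted by skipping the
#' bracketed keyword lines, provided its data block uses the same layout.
#'
#' @param path Path to the file.
#' @return A [TwoPortSweep-class].
#' @seealso [writeTouchstone()]
#' @export
readTouchstone <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unit <- 1e9; fmt <- "MA"; sawOption <- FALSE
  freq <- numeric(); vals <- list(); dataLine <- integer()
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) next   # v2 keyword line, e.g. [Version] 2.0
    if (startsWith(ln, "#")) {
      if (sawOption) next  # v1 spec: only the first option line counts
      sawOption <- TRUE
      toks <- tolower(strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]])
      j <- 1
      while (j <= length(toks)) {
        tk <- toks[j]
        if (tk %in% names(.tsUnits)) unit <- .tsUnits[[tk]]
        else if (tk %in% c("ri", "ma", "db")) fmt <- toupper(tk)
        else if (tk == "s") NULL
        else if (tk %in% c("y", "z", "g", "h"))
          stop("line ", i, ": only S-parameter files are supported")
        else if (tk == "r") j <- j + 1  # reference resistance value
        else stop("line ", i, ": malformed option line token '", tk, "'")
        j <- j + 1
      }
      next
    }
    toks <- strsplit(ln, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(toks))
    if (any(is.na(num)))
      stop("line ", i, ": non-numeric data token")
    if (length(num) != 9L)
      stop("line ", i, ": expected 9 columns (f + 4 S-parameters of a ",
           "2-port), got ", length(num))
    freq <- c(freq, num[1])
    vals[[length(vals) + 1L]] <- num[-1]
    dataLine <- c(dataLine, i)
  }
  if (!length(freq)) stop("no data rows found in ", path)
  if (any(diff(freq) <= 0)) {
    k <- which(diff(freq) <= 0)[1]
    stop("line ", dataLine[k + 1],
         ": frequencies are not strictly increasing")
  }
  m <- do.call(rbind, vals)
  toC <- switch(fmt,
    RI = function(a, b) complex(real = a, imaginary = b),
    MA = function(a, b) complex(modulus = a, argument = b * pi / 180),
    DB = function(a, b) complex(modulus = 10^(a / 20),
                                argument = b * pi / 180))
  twoPortSweep(freq * unit,
               s11 = toC(m[, 1], m[, 2]), s21 = toC(m[, 3], m[, 4]),
               s12 = toC(m[, 5], m[, 6]), s22 = toC(m[, 7], m[, 8]))
}

#' Write a two-port sweep as a Touchstone v1 .s2p file
#'
#' @param sweep A [TwoPortSweep-class].
#' @param path Output path.
#' @param unit Frequency unit for the file: `"Hz"` (default), `"kHz"`,
#'   `"MHz"` or `"GHz"`.
#' @param format `"RI"` (default), `"MA"` or `"DB"`.
#' @param comment Optional comment string written as a leading `!` line.
#' @return `path`, invisibly.
#' @export
writeTouchstone <- function(sweep, path, unit = "Hz", format = "RI",
                            comment = NULL) {
  stopifnot(is(sweep, "TwoPortSweep"))
  u <- .tsUnits[[tolower(unit)]]
  if (is.null(u)) stop("unknown frequency unit '", unit, "'")
  format <- match.arg(toupper(format), c("RI", "MA", "DB"))
  pair <- switch(format,
    RI = function(s) cbind(Re(s), Im(s)),
    MA = function(s) cbind(Mod(s), Arg(s) * 180 / pi),
    DB = function(s) cbind(20 * log10(Mod(s)), Arg(s) * 180 / pi))
  m <- cbind(sweep@frequencies / u,
             pair(sweep@s11), pair(sweep@s21),
             pair(sweep@s12), pair(sweep@s22))
  rows <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  header <- c(
    if (!is.null(comment)) paste("!", comment),
    sprintf("! coaxperm %s", as.character(packageVersion("coaxperm"))),
    sprintf("# %s S %s R 50", unit, format))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write a measurement set as a trio of .s2p files
#'
#' `writeMeasurementSetS2p()` writes `<prefix>_measurement.s2p`,
#' `<prefix>_short.s2p` and `<prefix>_empty.s2p` into `dir`;
#' `readMeasurementSetS2p()` rebuilds the [MeasurementSet-class] from three
#' such files plus a geometry.
#'
#' @param ms A [MeasurementSet-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `writeMeasurementSetS2p()`: named character vector of the three
#'   paths, invisibly.
#' @export
writeMeasurementSetS2p <- function(ms, dir, prefix = "specimen") {
  stopifnot(is(ms, "MeasurementSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    measurement = file.path(dir, paste0(prefix, "_measurement.s2p")),
    short = file.path(dir, paste0(prefix, "_short.s2p")),
    empty = file.path(dir, paste0(prefix, "_empty.s2p")))
  writeTouchstone(ms@measurement, paths[["measurement"]])
  writeTouchstone(ms@shortCircuit, paths[["short"]])
  writeTouchstone(ms@emptyCell, paths[["empty"]])
  invisible(paths)
}

#' @rdname writeMeasurementSetS2p
#' @param measurement,short,empty Paths to the three .s2p files.
#' @param geometry A [CellGeometry-class].
#' @param metadata Free-form list.
#' @export
readMeasurementSetS2p <- function(measurement, short, empty,
                                  geometry = cellGeometry(),
                                  metadata = list()) {
  measurementSet(readTouchstone(measurement), readTouchstone(short),
                 readTouchstone(empty), geometry = geometry,
                 metadata = metadata)
}
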