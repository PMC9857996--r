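# CSV I/O for titrations, kinetic traces and calibration series. Same
# fixed dialect as the spectral files: header row, comma separator, '.'
# decimal, 17 significant digits on write so round trips are lossless.

.readTwoColumn <- function(path, colA, colB) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, header = TRUE, strip.white = TRUE),
                 error = function(e) .stopf("cannot parse '%s': %s", path,
                                            conditionMessage(e)))
  if (nrow(df) == 0L) .stopf("'%s': no data rows", path)
  if (!all(c(colA, colB) %in% names(df)))
    .stopf("'%s': header must contain '%s' and '%s'", path, colA, colB)
  a <- suppressWarnings(as.numeric(df[[colA]]))
  b <- suppressWarnings(as.numeric(df[[colB]]))
  bad <- which(!is.finite(a) | !is.finite(b))
  if (length(bad)) .stopf("'%s': malformed row at line %d", path, bad[1L] + 1L)
  list(a = a, b = b)
}

.writeTwoColumn <- function(a, b, header, path) {
  writeLines(c(header, sprintf("%.17g,%.17g", a, b)), path)
  invisible(path)
}

#' Read/write a titration series
#'
#' Columns `ligand_total` and `intensity`; the ligand unit is declared by
#' flag (`"uM"` by default, matching instrument practice) and converted
#' to molar internally.
#'
#' @param path CSV path.
#' @param proteinTotal total protein concentration, in the same unit as
#'   the ligand column.
#' @param unit `"uM"` or `"M"`.
#' @param meta free-text conditions.
#' @return `readTitration`: a [TitrationSeries].
#' @export
readTitration <- function(path, proteinTotal, unit = c("uM", "M"), meta = "") {
  unit <- match.arg(unit)
  z <- .readTwoColumn(path, "ligand_total", "intensity")
  TitrationSeries(z$a, z$b, proteinTotal, unit = unit, meta = meta)
}

#' @rdname readTitration
#' @param series a [TitrationSeries] (written in uM).
#' @export
writeTitration <- function(series, path) {
  stopifnot(is(series, "TitrationSeries"))
  .writeTwoColumn(series@ligandTotal * 1e6, series@intensity,
                  "ligand_total,intensity", path)
}

#' Read/write a kinetic trace
#'
#' Columns `time_min` and `value`; whether `value` is A562 absorbance or
#' iron concentration (uM) is declared by flag, not guessed.
#'
#' @param path CSV path.
#' @param valueKind `"concentration"` or `"absorbance"`.
#' @param pathLength optical path, cm.
#' @return `readKineticTrace`: a [KineticTrace].
#' @export
readKineticTrace <- function(path,
                             valueKind = c("concentration", "absorbance"),
                             pathLength = 1) {
  valueKind <- match.arg(valueKind)
  z <- .readTwoColumn(path, "time_min", "value")
  KineticTrace(z$a, z$b, valueKind = valueKind, pathLength = pathLength)
}

#' @rdname readKineticTrace
#' @param trace a [KineticTrace].
#' @export
writeKineticTrace <- function(trace, path) {
  stopifnot(is(trace, "KineticTrace"))
  .writeTwoColumn(trace@times, trace@values, "time_min,value", path)
}

#' Read/write a calibration series
#'
#' Columns `conc_uM` and `a562`.
#'
#' @param path CSV path.
#' @return `readCalibration`: a data.frame with columns `conc_uM`,
#'   `a562`.
#' @export
readCalibration <- function(path) {
  z <- .readTwoColumn(path, "conc_uM", "a562")
  data.frame(conc_uM = z$a, a562 = z$b)
}

#' @rdname readCalibration
#' @param points a data.frame with columns `conc_uM` and `a562`.
#' @export
writeCalibration <- function(points, path) {
  .writeTwoColumn(points$conc_uM, points$a562, "conc_uM,a562", path)
}
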