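#' Read a spectrum from CSV
#'
#' The on-disk dialect is fixed: a header line `wavelength_nm,value`,
#' comma separator, `.` decimal. Rows are sorted by wavelength on read;
#' duplicated wavelengths are rejected (they would make the curve
#' ill-defined).
#'
#' @param path CSV file path.
#' @param kind spectrum kind: `"emission"`, `"absorption"`, or
#'   `"synchronous"`.
#' @param deltaLambda excitation-emission offset in nm, required when
#'   `kind = "synchronous"`.
#' @param label optional label; defaults to the file name.
#' @return A validated [Spectrum].
#' @seealso [writeSpectrum()] for the lossless inverse.
#' @export
readSpectrum <- function(path, kind = c("emission", "absorption", "synchronous"),
                         deltaLambda = NA_real_, label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .stopf("spectrum file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, strip.white = TRUE),
    error = function(e) .stopf("cannot parse '%s': %s", path, conditionMessage(e)))
  if (nrow(df) == 0L) .stopf("'%s': no data rows", path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    .stopf("'%s': header must be 'wavelength_nm,value' (got: %s)",
           path, paste(names(df), collapse = ","))
  w <- suppressWarnings(as.numeric(df$wavelength_nm))
  v <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(w) | !is.finite(v))
  if (length(bad))
    .stopf("'%s': malformed row at line %d", path, bad[1L] + 1L)
  dup <- which(duplicated(w))
  if (length(dup))
    .stopf("'%s': duplicated wavelength %g at line %d", path, w[dup[1L]],
           dup[1L] + 1L)
  Spectrum(w, v, kind = kind, deltaLambda = deltaLambda, label = label)
}

#' Write a spectrum to CSV
#'
#' Writes the fixed dialect read by [readSpectrum()], with enough digits
#' (17 significant) that a write/read round trip reproduces the numbers
#' exactly.
#'
#' @param s a [Spectrum].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(s, path) {
  stopifnot(is(s, "Spectrum"))
  validObject(s)
  lines <- c("wavelength_nm,value",
             sprintf("%.17g,%.17g", s@wavelength, s@values))
  writeLines(lines, path)
  invisible(path)
}

#' Locate the emission/absorption maximum
#'
#' The peak is the global argmax of the curve, optionally after
#' Savitzky-Golay (moving local-polynomial, order 2) smoothing. Only the
#' maximum position is reported -- no band-shape fitting -- which matches
#' how spectral shifts are read off scan maxima. Ties are broken toward
#' the lowest wavelength so the result is deterministic.
#'
#' @param s a [Spectrum] with at least 3 points.
#' @param smoothWindow odd window length in points for Savitzky-Golay
#'   smoothing, or `NULL` (default) for no smoothing.
#' @param allowTies if `FALSE` (default), a completely flat spectrum is an
#'   error (`"no unique peak"`); if `TRUE` the lowest wavelength is
#'   returned.
#' @return A [PeakReport].
#' @export
findPeak <- function(s, smoothWindow = NULL, allowTies = FALSE) {
  stopifnot(is(s, "Spectrum"))
  validObject(s)
  if (length(s) < 3L) .stopf("need at least 3 points to locate a peak")
  v <- s@values
  smoothed <- FALSE
  if (!is.null(smoothWindow)) {
    smoothWindow <- as.integer(smoothWindow)
    if (smoothWindow %% 2L == 0L || smoothWindow < 3L)
      .stopf("smoothWindow must be an odd integer >= 3")
    if (smoothWindow >= length(s))
      .stopf("smoothWindow (%d) must be smaller than the spectrum (%d points)",
             smoothWindow, length(s))
    v <- signal::sgolayfilt(v, p = min(2L, smoothWindow - 1L), n = smoothWindow)
    smoothed <- TRUE
  }
  if (!allowTies && diff(range(v)) == 0)
    .stopf("no unique peak: all values are equal")
  i <- which.max(v)  # first maximum = lowest wavelength on a sorted grid
  new("PeakReport", peakWavelength = s@wavelength[i], peakValue = v[i],
      smoothed = smoothed)
}

#' Peak shift between two spectra
#'
#' Signed displacement of the treated spectrum's maximum relative to the
#' reference: positive values are red shifts (toward longer wavelength,
#' i.e. a more hydrophilic fluorophore microenvironment), negative values
#' blue shifts.
#'
#' @param reference,treated two [Spectrum] objects of the same kind.
#' @param smoothWindow,allowTies passed to [findPeak()] for both spectra.
#' @return Shift in nm (treated peak minus reference peak).
#' @examples
#' grid <- 290:450
#' a <- Spectrum(grid, exp(-(grid - 327)^2 / 450), "emission")
#' b <- Spectrum(grid, exp(-(grid - 356)^2 / 450), "emission")
#' peakShift(a, b)  # +29
#' @export
peakShift <- function(reference, treated, smoothWindow = NULL,
                      allowTies = FALSE) {
  stopifnot(is(reference, "Spectrum"), is(treated, "Spectrum"))
  if (reference@kind != treated@kind)
    .stopf("peak shift requires spectra of the same kind (got %s vs %s)",
           reference@kind, treated@kind)
  findPeak(treated, smoothWindow, allowTies)@peakWavelength -
    findPeak(reference, smoothWindow, allowTies)@peakWavelength
}

#' Serialize a PeakReport to JSON
#'
#' @param report a [PeakReport].
#' @return A JSON string.
#' @export
peakReportJSON <- function(report) {
  stopifnot(is(report, "PeakReport"))
  jsonlite::toJSON(list(peak_wavelength_nm = report@peakWavelength,
                        peak_value = report@peakValue,
                        smoothed = report@smoothed),
                   auto_unbox = TRUE, digits = NA)
}
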