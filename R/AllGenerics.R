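#' Accessors
#'
#' Small accessor generics for the package's S4 containers; user code
#' should use these rather than reach into slots.
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))
#' @rdname accessors
#' @export
setGeneric("spectrumKind", function(x) standardGeneric("spectrumKind"))
#' @rdname accessors
#' @export
setGeneric("ligandTotals", function(x) standardGeneric("ligandTotals"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("proteinTotal", function(x) standardGeneric("proteinTotal"))
#' @rdname accessors
#' @export
setGeneric("bindingParams", function(x) standardGeneric("bindingParams"))
#' @rdname accessors
#' @export
setGeneric("fitWarnings", function(x) standardGeneric("fitWarnings"))
#' @rdname accessors
#' @export
setGeneric("initialRate", function(x) standardGeneric("initialRate"))

#' @rdname accessors
setMethod("wavelengths", "Spectrum", function(x) x@wavelength)
#' @rdname accessors
setMethod("spectrumValues", "Spectrum", function(x) x@values)
#' @rdname accessors
setMethod("spectrumKind", "Spectrum", function(x) x@kind)
#' @rdname accessors
setMethod("ligandTotals", "TitrationSeries", function(x) x@ligandTotal)
#' @rdname accessors
setMethod("intensities", "TitrationSeries", function(x) x@intensity)
#' @rdname accessors
setMethod("proteinTotal", "TitrationSeries", function(x) x@proteinTotal)
#' @rdname accessors
setMethod("bindingParams", "BindingFit", function(x) x@params)
#' @rdname accessors
setMethod("fitWarnings", "BindingFit", function(x) x@warnings)
#' @rdname accessors
setMethod("fitWarnings", "CubicFit", function(x) x@warnings)
#' @rdname accessors
setMethod("initialRate", "CubicFit", function(x) x@v0)

setMethod("length", "Spectrum", function(x) length(x@wavelength))
setMethod("length", "TitrationSeries", function(x) length(x@ligandTotal))
setMethod("length", "KineticTrace", function(x) length(x@times))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, %.6g-%.6g nm",
              object@kind, length(object@wavelength),
              min(object@wavelength), max(object@wavelength)))
  if (object@kind == "synchronous")
    cat(sprintf(", delta-lambda %g nm", object@deltaLambda))
  if (nzchar(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
})

setMethod("show", "PeakReport", function(object) {
  cat(sprintf("Peak at %.6g nm (value %.6g%s)\n", object@peakWavelength,
              object@peakValue, if (object@smoothed) ", smoothed" else ""))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: %d points, [P]0 = %.4g uM, ligand %.4g-%.4g uM\n",
    length(object@ligandTotal), object@proteinTotal * 1e6,
    min(object@ligandTotal) * 1e6, max(object@ligandTotal) * 1e6))
  if (nzchar(object@meta)) cat("  ", object@meta, "\n", sep = "")
})

setMethod("show", "BindingParams", function(object) {
  cat(sprintf(
    "BindingParams: I0 = %.4g, Iinf = %.4g, n = %.4g sites, K = %.4g M^-1\n",
    object@I0, object@Iinf, object@n, object@K))
})

setMethod("show", "BindingFit", function(object) {
  p <- object@params
  cat("Ligand-depletion quenching fit\n")
  cat(sprintf("  n = %.4g +/- %.3g sites per protein\n",
              p@n, object@stderr["n"]))
  cat(sprintf("  K = %.4g +/- %.3g M^-1\n", p@K, object@stderr["K"]))
  cat(sprintf("  I0 = %.4g, Iinf = %.4g, rss = %.4g (%d starts)\n",
              p@I0, p@Iinf, object@rss, object@nStartsUsed))
  for (w in object@warnings) cat("  warning: ", w, "\n", sep = "")
})

setMethod("show", "FretConstants", function(object) {
  cat(sprintf(
    "FretConstants: kappa2 = %.4g, phi = %.4g, n = %.4g, convention = %s\n",
    object@kappa2, object@phi, object@refIndex, object@convention))
})

setMethod("show", "FretResult", function(object) {
  cat("FRET spectroscopic ruler\n")
  cat(sprintf("  J  = %.4g M^-1 cm^-1 nm^4 (= %.4g cm^3 M^-1)\n",
              object@J, object@Jcm3))
  cat(sprintf("  R0 = %.4g nm (%s)\n", object@R0, object@convention))
  cat(sprintf("  E  = %.4g, r = %.4g nm\n", object@E, object@r))
  cat(sprintf("  r < 7 nm: %s; 0.5 R0 < r < 2 R0: %s\n",
              object@validDistance, object@validRange))
})

setMethod("show", "KineticTrace", function(object) {
  cat(sprintf("KineticTrace (%s): %d points, %.4g-%.4g min\n",
              object@valueKind, length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "CubicFit", function(object) {
  co <- object@coefficients
  cat(sprintf(
    "Cubic progress-curve fit: Y = %.4g + %.4g t + %.4g t^2 + %.4g t^3 (uM)\n",
    co["A0"], co["A1"], co["A2"], co["A3"]))
  cat(sprintf("  v0 = %.4g nM/min, rss = %.4g\n", object@v0, object@rss))
  for (w in object@warnings) cat("  warning: ", w, "\n", sep = "")
})

setMethod("show", "InhibitionResult", function(object) {
  cat(sprintf("Iron release: %.4g uM -> %.4g uM, decrease %.2f%%\n",
              object@baselineReleased, object@treatedReleased,
              round(object@percentDecrease, 2)))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "FeSO4 standard curve: A562 = %.4g * c(uM) + %.4g, r2 = %.4f (%d points)\n",
    object@slope, object@intercept, object@r2, length(object@concentrations)))
})
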