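#' @import methods
NULL

.SPECTRUM_KINDS <- c("emission", "absorption", "synchronous")

#' Spectrum: a wavelength-indexed curve
#'
#' Container for a single spectroscopic scan: an emission spectrum
#' (intensity, arbitrary units), an absorption spectrum (molar
#' absorptivity, M^-1 cm^-1), or a synchronous scan recorded at a fixed
#' excitation-emission offset `deltaLambda` (nm). Wavelengths are always
#' nanometres and strictly increasing.
#'
#' @slot wavelength numeric, nm, strictly increasing.
#' @slot values numeric, same length as `wavelength`; intensity (a.u.) for
#'   emission/synchronous spectra, molar absorptivity (M^-1 cm^-1, must be
#'   non-negative) for absorption spectra.
#' @slot kind one of `"emission"`, `"absorption"`, `"synchronous"`.
#' @slot deltaLambda nm; required (finite, > 0) for synchronous scans,
#'   `NA` otherwise. Offsets of 15 nm and 60 nm select tyrosine and
#'   tryptophan microenvironments respectively.
#' @slot label free-text description.
#' @export
setClass("Spectrum",
  slots = c(
    wavelength = "numeric",
    values = "numeric",
    kind = "character",
    deltaLambda = "numeric",
    label = "character"
  ),
  prototype = prototype(deltaLambda = NA_real_, label = "")
)

setValidity("Spectrum", function(object) {
  w <- object@wavelength
  v <- object@values
  msgs <- character()
  if (length(w) != length(v))
    msgs <- c(msgs, "wavelength and values must have equal length")
  if (length(w) < 1L)
    msgs <- c(msgs, "spectrum must contain at least one point")
  if (!all(is.finite(w)) || !all(is.finite(v)))
    msgs <- c(msgs, "wavelengths and values must all be finite")
  if (length(w) > 1L && any(diff(w) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.SPECTRUM_KINDS, collapse = ", ")))
  else {
    if (object@kind == "absorption" && any(v < 0))
      msgs <- c(msgs, "absorption values (molar absorptivity) must be non-negative")
    if (object@kind == "synchronous" &&
        (length(object@deltaLambda) != 1L || !is.finite(object@deltaLambda) ||
         object@deltaLambda <= 0))
      msgs <- c(msgs, "synchronous spectra must carry a positive deltaLambda (nm)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname Spectrum-class
#' @param wavelength,values,kind,deltaLambda,label see slots.
#' @return A validated `Spectrum`.
#' @examples
#' s <- Spectrum(300:310, dnorm(300:310, 305, 3), kind = "emission")
#' @export
Spectrum <- function(wavelength, values, kind = "emission",
                     deltaLambda = NA_real_, label = "") {
  ord <- order(wavelength)
  new("Spectrum",
      wavelength = as.numeric(wavelength)[ord],
      values = as.numeric(values)[ord],
      kind = kind, deltaLambda = as.numeric(deltaLambda),
      label = as.character(label))
}

#' PeakReport: located spectral maximum
#'
#' @slot peakWavelength nm of the global maximum (ties broken toward the
#'   lowest wavelength).
#' @slot peakValue value at the maximum, in the spectrum's units (taken
#'   from the smoothed curve when smoothing was applied).
#' @slot smoothed whether Savitzky-Golay smoothing preceded the search.
#' @export
setClass("PeakReport",
  slots = c(peakWavelength = "numeric", peakValue = "numeric",
            smoothed = "logical"))

#' TitrationSeries: fluorescence-quenching titration
#'
#' Fluorescence intensity of a fixed amount of protein as total ligand is
#' increased. Concentrations are molar internally; readers accept
#' micromolar input with a unit flag.
#'
#' @slot ligandTotal total ligand concentration, M, non-negative and
#'   non-decreasing (the first point may be 0).
#' @slot intensity fluorescence intensity, a.u.
#' @slot proteinTotal total protein concentration, M (> 0), length 1.
#' @slot meta free-text buffer/pH/temperature description.
#' @export
setClass("TitrationSeries",
  slots = c(ligandTotal = "numeric", intensity = "numeric",
            proteinTotal = "numeric", meta = "character"),
  prototype = prototype(meta = ""))

setValidity("TitrationSeries", function(object) {
  msgs <- character()
  if (length(object@ligandTotal) != length(object@intensity))
    msgs <- c(msgs, "ligandTotal and intensity must have equal length")
  if (!all(is.finite(object@ligandTotal)) || !all(is.finite(object@intensity)))
    msgs <- c(msgs, "ligandTotal and intensity must be finite")
  if (any(object@ligandTotal < 0))
    msgs <- c(msgs, "ligandTotal must be non-negative")
  if (length(object@ligandTotal) > 1L && any(diff(object@ligandTotal) < 0))
    msgs <- c(msgs, "ligandTotal must be non-decreasing")
  if (length(object@proteinTotal) != 1L || !is.finite(object@proteinTotal) ||
      object@proteinTotal <= 0)
    msgs <- c(msgs, "proteinTotal must be a single positive concentration (M)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TitrationSeries-class
#' @param ligandTotal,intensity,proteinTotal,meta see slots.
#' @param unit `"M"` or `"uM"`; concentrations are converted to molar.
#' @export
TitrationSeries <- function(ligandTotal, intensity, proteinTotal,
                            unit = c("M", "uM"), meta = "") {
  unit <- match.arg(unit)
  f <- if (unit == "uM") 1e-6 else 1
  new("TitrationSeries",
      ligandTotal = as.numeric(ligandTotal) * f,
      intensity = as.numeric(intensity),
      proteinTotal = as.numeric(proteinTotal) * f,
      meta = as.character(meta))
}

#' BindingParams: parameters of the ligand-depletion quenching isotherm
#'
#' The model tracks free vs. total ligand exactly through the quadratic
#' mass-action solution for n identical independent sites per protein, so
#' it remains valid when the ligand is not in vast excess over the
#' binding sites.
#'
#' @slot I0 intensity without ligand, a.u.
#' @slot Iinf intensity at full site saturation, a.u. (`I0 >= Iinf >= 0`
#'   for a quenching system).
#' @slot n binding sites per protein molecule, dimensionless, > 0.
#' @slot K per-site association constant, M^-1, > 0.
#' @export
setClass("BindingParams",
  slots = c(I0 = "numeric", Iinf = "numeric", n = "numeric", K = "numeric"))

setValidity("BindingParams", function(object) {
  v <- c(object@I0, object@Iinf, object@n, object@K)
  msgs <- character()
  if (length(v) != 4L || !all(is.finite(v)))
    msgs <- c(msgs, "I0, Iinf, n, K must be single finite numbers")
  else {
    if (object@n <= 0) msgs <- c(msgs, "n must be > 0")
    if (object@K <= 0) msgs <- c(msgs, "K must be > 0")
    if (object@Iinf < 0 || object@I0 < object@Iinf)
      msgs <- c(msgs, "quenching requires I0 >= Iinf >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname BindingParams-class
#' @param I0,Iinf,n,K see slots.
#' @export
BindingParams <- function(I0, Iinf, n, K) {
  new("BindingParams", I0 = as.numeric(I0), Iinf = as.numeric(Iinf),
      n = as.numeric(n), K = as.numeric(K))
}

#' BindingFit: fitted quenching isotherm
#'
#' @slot params the best-fit [BindingParams].
#' @slot stderr named numeric (`n`, `K`): asymptotic standard errors from
#'   the local curvature at the optimum (`K` by the delta method on
#'   log10 K); `NA` when the curvature is singular.
#' @slot rss residual sum of squares, a.u.^2.
#' @slot converged whether at least one start converged.
#' @slot nStartsUsed number of starting points attempted.
#' @slot warnings diagnostic messages (e.g. missing saturating tail).
#' @export
setClass("BindingFit",
  slots = c(params = "BindingParams", stderr = "numeric", rss = "numeric",
            converged = "logical", nStartsUsed = "integer",
            warnings = "character"))

setValidity("BindingFit", function(object) {
  msgs <- character()
  if (length(object@rss) != 1L || !is.finite(object@rss) || object@rss < 0)
    msgs <- c(msgs, "rss must be a single non-negative number")
  se <- object@stderr
  if (!all(c("n", "K") %in% names(se)))
    msgs <- c(msgs, "stderr must carry elements named n and K")
  else if (any(!is.na(se) & se < 0))
    msgs <- c(msgs, "standard errors must be non-negative when reported")
  if (length(msgs)) msgs else TRUE
})

#' FretConstants: photophysical constants of the donor-acceptor pair
#'
#' Defaults are the tryptophan-donor values used for intrinsic protein
#' fluorescence: isotropic-average orientation factor kappa^2 = 2/3,
#' donor quantum yield 0.118, and refractive index 1.366 (average of
#' water and organic solute).
#'
#' Two conventions for the Forster-radius prefactor are provided because
#' published forms differ in units:
#' * `"standard_A6"`: R0^6 (Angstrom^6) = 8.79e-5 * kappa^2 * n^-4 * phi * J
#'   with J in M^-1 cm^-1 nm^4 (the widely used form).
#' * `"paper_literal"`: R0^6 = 8.79e25 * kappa^2 * n^-4 * phi * J with J in
#'   cm^3 M^-1, the result read as Angstrom^6.
#'
#' @slot kappa2 orientation factor, in (0, 4].
#' @slot phi donor quantum yield, in (0, 1].
#' @slot refIndex medium refractive index, >= 1.
#' @slot convention `"standard_A6"` or `"paper_literal"`.
#' @export
setClass("FretConstants",
  slots = c(kappa2 = "numeric", phi = "numeric", refIndex = "numeric",
            convention = "character"))

setValidity("FretConstants", function(object) {
  msgs <- character()
  if (!is.finite(object@kappa2) || object@kappa2 <= 0 || object@kappa2 > 4)
    msgs <- c(msgs, "kappa2 must lie in (0, 4]")
  if (!is.finite(object@phi) || object@phi <= 0 || object@phi > 1)
    msgs <- c(msgs, "phi must lie in (0, 1]")
  if (!is.finite(object@refIndex) || object@refIndex < 1)
    msgs <- c(msgs, "refIndex must be >= 1")
  if (!object@convention %in% c("standard_A6", "paper_literal"))
    msgs <- c(msgs, "convention must be 'standard_A6' or 'paper_literal'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname FretConstants-class
#' @param kappa2,phi,refIndex,convention see slots.
#' @export
FretConstants <- function(kappa2 = 2 / 3, phi = 0.118, refIndex = 1.366,
                          convention = c("standard_A6", "paper_literal")) {
  convention <- match.arg(convention)
  new("FretConstants", kappa2 = kappa2, phi = phi, refIndex = refIndex,
      convention = convention)
}

#' FretResult: the spectroscopic-ruler chain
#'
#' @slot J overlap integral, M^-1 cm^-1 nm^4 (native unit).
#' @slot Jcm3 the same J expressed in cm^3 M^-1 (x 1e-28).
#' @slot R0 Forster radius, nm.
#' @slot E transfer efficiency, fraction in [0, 1].
#' @slot r donor-acceptor distance, nm.
#' @slot validDistance TRUE when r < 7 nm.
#' @slot validRange TRUE when 0.5 R0 < r < 2 R0 (strict).
#' @slot convention the prefactor convention used for R0.
#' @export
setClass("FretResult",
  slots = c(J = "numeric", Jcm3 = "numeric", R0 = "numeric", E = "numeric",
            r = "numeric", validDistance = "logical", validRange = "logical",
            convention = "character"))

setValidity("FretResult", function(object) {
  msgs <- character()
  if (!is.finite(object@E) || object@E < 0 || object@E > 1)
    msgs <- c(msgs, "E must lie in [0, 1]")
  if (any(c(object@J, object@R0, object@r) < 0, na.rm = TRUE))
    msgs <- c(msgs, "J, R0 and r must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' KineticTrace: iron-release progress curve
#'
#' Time course of the ferrozine assay, either as raw A562 absorbance or
#' as iron concentration after Beer-Lambert conversion.
#'
#' @slot times minutes, non-negative, strictly increasing.
#' @slot values A562 (dimensionless) or iron concentration (uM).
#' @slot valueKind `"absorbance"` or `"concentration"`.
#' @slot pathLength cuvette path, cm (default 1).
#' @export
setClass("KineticTrace",
  slots = c(times = "numeric", values = "numeric", valueKind = "character",
            pathLength = "numeric"),
  prototype = prototype(pathLength = 1))

setValidity("KineticTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (!all(is.finite(object@times)) || !all(is.finite(object@values)))
    msgs <- c(msgs, "times and values must be finite")
  if (any(object@times < 0))
    msgs <- c(msgs, "times must be non-negative")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (!object@valueKind %in% c("absorbance", "concentration"))
    msgs <- c(msgs, "valueKind must be 'absorbance' or 'concentration'")
  if (length(object@pathLength) != 1L || !is.finite(object@pathLength) ||
      object@pathLength <= 0)
    msgs <- c(msgs, "pathLength must be a single positive number (cm)")
  if (length(msgs)) msgs else TRUE
})

#' @rdname KineticTrace-class
#' @param times,values,valueKind,pathLength see slots.
#' @export
KineticTrace <- function(times, values,
                         valueKind = c("concentration", "absorbance"),
                         pathLength = 1) {
  valueKind <- match.arg(valueKind)
  new("KineticTrace", times = as.numeric(times), values = as.numeric(values),
      valueKind = valueKind, pathLength = as.numeric(pathLength))
}

#' CubicFit: third-order progress-curve fit
#'
#' Ordinary least squares of Y = A0 + A1 t + A2 t^2 + A3 t^3 on the
#' concentration scale; the initial release rate is the t = 0 slope,
#' v0 = A1, reported in nM/min.
#'
#' @slot coefficients named numeric `A0` (uM), `A1` (uM/min),
#'   `A2` (uM/min^2), `A3` (uM/min^3).
#' @slot v0 initial rate, nM/min; always exactly `A1 * 1000`.
#' @slot rss residual sum of squares, uM^2.
#' @slot warnings e.g. a negative fitted initial rate (reported, never
#'   clamped).
#' @export
setClass("CubicFit",
  slots = c(coefficients = "numeric", v0 = "numeric", rss = "numeric",
            warnings = "character"))

setValidity("CubicFit", function(object) {
  msgs <- character()
  if (!identical(names(object@coefficients), c("A0", "A1", "A2", "A3")))
    msgs <- c(msgs, "coefficients must be named A0, A1, A2, A3")
  else if (!isTRUE(all.equal(object@v0, unname(object@coefficients["A1"]) * 1000)))
    msgs <- c(msgs, "v0 must equal A1 * 1000 (nM/min)")
  if (!is.finite(object@rss) || object@rss < 0)
    msgs <- c(msgs, "rss must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' InhibitionResult: percent decrease in released iron
#'
#' @slot baselineReleased iron released without inhibitor, uM.
#' @slot treatedReleased iron released with inhibitor, uM.
#' @slot percentDecrease 100 * (baseline - treated) / baseline, exact.
#'   Reports round to 2 decimal places (round-half-even).
#' @export
setClass("InhibitionResult",
  slots = c(baselineReleased = "numeric", treatedReleased = "numeric",
            percentDecrease = "numeric"))

#' StandardCurve: FeSO4 ferrozine calibration line
#'
#' @slot concentrations uM.
#' @slot absorbances A562.
#' @slot slope A562 per uM.
#' @slot intercept A562.
#' @slot r2 coefficient of determination, in [0, 1].
#' @export
setClass("StandardCurve",
  slots = c(concentrations = "numeric", absorbances = "numeric",
            slope = "numeric", intercept = "numeric", r2 = "numeric"))

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (length(object@concentrations) < 3L)
    msgs <- c(msgs, "a standard curve needs at least 3 points")
  if (length(object@concentrations) != length(object@absorbances))
    msgs <- c(msgs, "concentrations and absorbances must have equal length")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1 + 1e-12))
    msgs <- c(msgs, "r2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
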