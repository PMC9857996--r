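#' Iron concentration from ferrozine absorbance
#'
#' Beer-Lambert conversion of the [Fe(ferrozine)3]2+ complex absorbance
#' at 562 nm: `c (uM) = 1000 * A562 / (epsilon * path)`, with the
#' complex's molar absorptivity `epsilon = 27.9 mM^-1 cm^-1` by default.
#'
#' @param a562 absorbance at 562 nm (>= 0); may be a vector.
#' @param epsilonmM molar absorptivity, mM^-1 cm^-1 (> 0).
#' @param pathLength optical path, cm (> 0).
#' @return Iron concentration in uM.
#' @examples
#' concFromAbsorbance(0.0279)  # 1 uM
#' @export
concFromAbsorbance <- function(a562, epsilonmM = 27.9, pathLength = 1) {
  if (any(!is.finite(a562)) || any(a562 < 0))
    .stopf("absorbance must be finite and non-negative")
  if (!is.finite(epsilonmM) || epsilonmM <= 0 ||
      !is.finite(pathLength) || pathLength <= 0)
    .stopf("epsilon and path length must be positive")
  1000 * a562 / (epsilonmM * pathLength)
}

#' Convert a kinetic trace to the concentration scale
#'
#' @param trace a [KineticTrace]; returned unchanged if already in
#'   concentration units.
#' @param epsilonmM molar absorptivity, mM^-1 cm^-1.
#' @return A [KineticTrace] with `valueKind = "concentration"` (uM).
#' @export
asConcentration <- function(trace, epsilonmM = 27.9) {
  stopifnot(is(trace, "KineticTrace"))
  validObject(trace)
  if (trace@valueKind == "concentration") return(trace)
  KineticTrace(trace@times,
               concFromAbsorbance(trace@values, epsilonmM, trace@pathLength),
               valueKind = "concentration", pathLength = trace@pathLength)
}

#' Cubic fit of an iron-release progress curve
#'
#' Ordinary least squares of `Y = A0 + A1 t + A2 t^2 + A3 t^3` on the
#' concentration scale. Since `dY/dt = A1 + 2 A2 t + 3 A3 t^2`, the
#' initial release rate is the linear coefficient: `v0 = A1`, reported in
#' nM/min. A negative fitted `v0` is physically suspect and is flagged
#' with a warning but never clamped.
#'
#' @param trace a [KineticTrace] in concentration units (uM) with at
#'   least 5 points over at least 4 distinct times; convert absorbance
#'   traces with [asConcentration()] first.
#' @return A [CubicFit].
#' @export
fitCubic <- function(trace) {
  stopifnot(is(trace, "KineticTrace"))
  validObject(trace)
  if (trace@valueKind != "concentration")
    .stopf("fitCubic expects a concentration trace; use asConcentration() first")
  t <- trace@times
  y <- trace@values
  if (length(t) < 5L) .stopf("need at least 5 time points for a cubic fit")
  if (length(unique(t)) < 4L)
    .stopf("rank-deficient design: need at least 4 distinct times")
  fit <- stats::lm(y ~ t + I(t^2) + I(t^3))
  co <- unname(stats::coef(fit))
  co[is.na(co)] <- 0
  names(co) <- c("A0", "A1", "A2", "A3")
  warns <- character()
  if (co["A1"] < 0)
    warns <- "fitted initial rate is negative"
  new("CubicFit", coefficients = co, v0 = unname(co["A1"]) * 1000,
      rss = sum(stats::residuals(fit)^2), warnings = warns)
}

#' Percent decrease in released iron
#'
#' `100 * (baseline - treated) / baseline`, the fractional inhibition of
#' iron release by the protein-polyphenol interaction. The exact value is
#' stored; reports round to 2 decimal places (round-half-even).
#'
#' @param baseline iron released without inhibitor, uM (> 0).
#' @param treated iron released with inhibitor, uM (>= 0).
#' @return An [InhibitionResult].
#' @examples
#' percentInhibition(1.16, 0.16)  # 86.21% decrease
#' @export
percentInhibition <- function(baseline, treated) {
  if (!is.finite(baseline) || baseline <= 0)
    .stopf("baseline released iron must be positive")
  if (!is.finite(treated) || treated < 0)
    .stopf("treated released iron must be non-negative")
  new("InhibitionResult", baselineReleased = baseline,
      treatedReleased = treated,
      percentDecrease = 100 * (baseline - treated) / baseline)
}

#' Fit the FeSO4 calibration line
#'
#' Least-squares line through concentration/absorbance pairs, used to
#' check that the ferrozine readout is unaffected by the protein or the
#' buffer.
#'
#' @param concentrations FeSO4 concentrations, uM (at least 3 distinct).
#' @param absorbances matching A562 readings.
#' @return A [StandardCurve] with slope (A562 per uM), intercept and r2.
#' @export
fitStandardCurve <- function(concentrations, absorbances) {
  if (length(concentrations) < 3L)
    .stopf("need at least 3 calibration points")
  if (length(concentrations) != length(absorbances))
    .stopf("concentrations and absorbances must have equal length")
  if (stats::var(concentrations) == 0)
    .stopf("calibration concentrations have zero variance")
  fit <- stats::lm(absorbances ~ concentrations)
  co <- stats::coef(fit)
  tss <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  new("StandardCurve", concentrations = as.numeric(concentrations),
      absorbances = as.numeric(absorbances),
      slope = unname(co[2]), intercept = unname(co[1]),
      r2 = min(max(r2, 0), 1))
}

#' Equivalence of two calibration lines
#'
#' Operational rule for "the readout does not differ between groups":
#' slopes must agree within `relTol` (relative to the first curve's
#' slope) and intercepts within `relTol` of the first curve's full-scale
#' signal (`slope * refConc`).
#'
#' @param a,b two [StandardCurve] objects (`a` is the reference).
#' @param relTol relative tolerance, default 0.05.
#' @param refConc full-scale concentration for the intercept criterion,
#'   uM (default 50, the top of the calibration range).
#' @return `TRUE` when the curves are equivalent.
#' @export
curvesEquivalent <- function(a, b, relTol = 0.05, refConc = 50) {
  stopifnot(is(a, "StandardCurve"), is(b, "StandardCurve"))
  abs(a@slope - b@slope) / abs(a@slope) <= relTol &&
    abs(a@intercept - b@intercept) <= relTol * abs(a@slope) * refConc
}

#' Released iron at the end of a trace
#'
#' The reported "released iron after 60 min" is the last measured
#' concentration, not a fitted-curve evaluation.
#'
#' @param trace a [KineticTrace] in concentration units.
#' @return Final concentration, uM.
#' @export
finalRelease <- function(trace) {
  stopifnot(is(trace, "KineticTrace"))
  if (trace@valueKind != "concentration")
    .stopf("finalRelease expects a concentration trace")
  trace@values[length(trace@values)]
}

#' Serialize kinetics results to JSON
#'
#' @param x a [CubicFit], [InhibitionResult], or [StandardCurve].
#' @return A JSON string.
#' @export
kineticsJSON <- function(x) {
  out <- if (is(x, "CubicFit")) {
    c(as.list(x@coefficients),
      list(v0_nM_per_min = x@v0, rss = x@rss, warnings = x@warnings))
  } else if (is(x, "InhibitionResult")) {
    list(baseline_released_uM = x@baselineReleased,
         treated_released_uM = x@treatedReleased,
         percent_decrease = round(x@percentDecrease, 2))
  } else if (is(x, "StandardCurve")) {
    list(slope_per_uM = x@slope, intercept = x@intercept, r2 = x@r2)
  } else .stopf("unsupported object of class %s", class(x)[1])
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}
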