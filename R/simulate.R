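# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments: the RNG state is set from (seed, substream) and restored
# afterwards, so call order never leaks between generators. Defaults
# mirror the study conditions (1.0 uM protein, ligand 0-50 uM, 60 min
# release window, 10-50 uM FeSO4 calibration); noise is additive Gaussian
# with a standard deviation expressed as a fraction of the signal
# amplitude.

#' Simulate a fluorescence-quenching titration
#'
#' Evaluates the ligand-depletion isotherm at the given truth and adds
#' Gaussian noise with sd `noiseSd * I0`.
#'
#' @param truth generating [BindingParams]; the default is the
#'   protein-polyphenol system's fitted values (I0 = 100, Iinf = 20,
#'   n = 22.11 sites, K = 4.99e5 M^-1).
#' @param proteinTotal total protein, M (default 1 uM).
#' @param ligandTotals total-ligand grid, M, non-decreasing (default
#'   0-50 uM in 1 uM steps).
#' @param noiseSd Gaussian noise sd as a fraction of `I0`.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return A [TitrationSeries].
#' @export
simulateTitration <- function(truth = BindingParams(100, 20, 22.11, 4.99e5),
                              proteinTotal = 1e-6,
                              ligandTotals = seq(0, 50e-6, by = 1e-6),
                              noiseSd = 0.01, seed = 1) {
  stopifnot(is(truth, "BindingParams"), noiseSd >= 0)
  clean <- bindingIntensity(truth, proteinTotal, ligandTotals)
  noisy <- .withSeed(.substreamSeed(seed, "titration"),
                     clean + stats::rnorm(length(clean),
                                          sd = noiseSd * truth@I0))
  TitrationSeries(ligandTotals, noisy, proteinTotal, unit = "M",
                  meta = sprintf("synthetic titration (seed %d)", seed))
}

.gaussBand <- function(grid, center, width, amp) {
  amp * exp(-(grid - center)^2 / (2 * width^2))
}

#' Simulate a donor-emission / acceptor-absorption spectrum pair
#'
#' Parametric Gaussian bands on a common wavelength grid, emulating the
#' overlap of a tryptophan emission spectrum with a polyphenol
#' absorption band. Defaults place the donor maximum at 327 nm (the
#' unbound protein's emission peak).
#'
#' @param donorCenter,donorWidth,donorAmp donor band: center nm, Gaussian
#'   sd nm, peak intensity a.u.
#' @param acceptorCenter,acceptorWidth,acceptorEpsMax acceptor band:
#'   center nm, Gaussian sd nm, peak molar absorptivity M^-1 cm^-1.
#' @param grid wavelength grid, nm (default 250-500 by 1 nm).
#' @param noiseSd Gaussian noise sd as a fraction of each band's peak;
#'   acceptor noise is truncated at zero (absorptivity cannot be
#'   negative).
#' @param seed integer seed.
#' @return A list with elements `donor` and `acceptor`, both [Spectrum].
#' @export
simulateSpectrumPair <- function(donorCenter = 327, donorWidth = 22,
                                 donorAmp = 100,
                                 acceptorCenter = 322, acceptorWidth = 28,
                                 acceptorEpsMax = 15000,
                                 grid = seq(250, 500, by = 1),
                                 noiseSd = 0, seed = 1) {
  stopifnot(donorWidth > 0, acceptorWidth > 0, noiseSd >= 0)
  dv <- .gaussBand(grid, donorCenter, donorWidth, donorAmp)
  av <- .gaussBand(grid, acceptorCenter, acceptorWidth, acceptorEpsMax)
  if (noiseSd > 0) {
    noise <- .withSeed(.substreamSeed(seed, "spectra"),
                       list(d = stats::rnorm(length(grid),
                                             sd = noiseSd * donorAmp),
                            a = stats::rnorm(length(grid),
                                             sd = noiseSd * acceptorEpsMax)))
    dv <- dv + noise$d
    av <- pmax(av + noise$a, 0)
  }
  list(donor = Spectrum(grid, dv, "emission", label = "synthetic donor"),
       acceptor = Spectrum(grid, av, "absorption",
                           label = "synthetic acceptor"))
}

#' Simulate an iron-release progress curve
#'
#' Two truth models are available: a cubic polynomial (matching the
#' fitted form) with `params = c(A0, A1, A2, A3)` in uM and powers of
#' minutes, and a saturating exponential
#' `Y = Ymax (1 - exp(-k t))` with `params = c(Ymax, k)` (initial rate
#' `Ymax * k`), which is the more realistic shape for release
#' approaching a plateau.
#'
#' @param model `"cubic"` or `"saturating_exponential"`.
#' @param params model parameters, see above.
#' @param times time grid, min (default 0-60 by 2.5).
#' @param noiseSd Gaussian noise sd as a fraction of the trace amplitude.
#' @param seed integer seed.
#' @return A [KineticTrace] in concentration units (uM).
#' @export
simulateKineticTrace <- function(model = c("saturating_exponential", "cubic"),
                                 params = c(Ymax = 1.16, k = 0.09986 / 1.16),
                                 times = seq(0, 60, by = 2.5),
                                 noiseSd = 0, seed = 1) {
  model <- match.arg(model)
  stopifnot(noiseSd >= 0)
  y <- switch(model,
    cubic = {
      stopifnot(length(params) == 4L)
      params[1] + params[2] * times + params[3] * times^2 +
        params[4] * times^3
    },
    saturating_exponential = {
      stopifnot(length(params) == 2L)
      params[1] * (1 - exp(-params[2] * times))
    })
  if (noiseSd > 0) {
    amp <- max(abs(y))
    y <- .withSeed(.substreamSeed(seed, "kinetics"),
                   y + stats::rnorm(length(y), sd = noiseSd * amp))
  }
  KineticTrace(times, y, valueKind = "concentration")
}

#' Simulate an FeSO4 calibration series
#'
#' Absorbances on a straight line `A = slope * c + intercept` with
#' additive Gaussian noise. The default slope is the Beer-Lambert value
#' for the iron-ferrozine complex (27.9 mM^-1 cm^-1, i.e. 0.0279 A562
#' per uM at 1 cm), so a noise-free series round-trips exactly through
#' [concFromAbsorbance()].
#'
#' @param slopePerUM A562 per uM (> 0).
#' @param intercept A562 at zero iron.
#' @param concentrations uM grid (default 10-50 by 10).
#' @param noiseSd Gaussian noise sd as a fraction of the full-scale
#'   absorbance `slopePerUM * max(concentrations)`.
#' @param seed integer seed.
#' @return A data.frame with columns `conc_uM` and `a562`.
#' @export
simulateStandardCurve <- function(slopePerUM = 0.0279, intercept = 0,
                                  concentrations = seq(10, 50, by = 10),
                                  noiseSd = 0, seed = 1) {
  stopifnot(slopePerUM > 0, noiseSd >= 0)
  a <- slopePerUM * concentrations + intercept
  if (noiseSd > 0) {
    amp <- slopePerUM * max(concentrations)
    a <- .withSeed(.substreamSeed(seed, "calibration"),
                   a + stats::rnorm(length(a), sd = noiseSd * amp))
  }
  data.frame(conc_uM = concentrations, a562 = a)
}
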