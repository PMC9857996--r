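---
title: "Models and methods in specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind implements the spectroscopic analysis chain used to characterize
a protein–polyphenol interaction — here, barley-malt protein Z (a ~40 kDa
serpin-family protein carrying tryptophan fluorophores) binding ferulic
acid — and its downstream consequence, the inhibition of iron release from
ferritin measured by the ferrozine assay. This vignette explains each
model, its assumptions, the tunable parameters, and the choices made where
the design was genuinely open.

## The ligand-depletion quenching isotherm

Titrating the protein with the quenching ligand and reading fluorescence
intensity gives the binding stoichiometry *n* and per-site association
constant *K*. Because the ligand here is comparable in concentration to
the site pool (micromolar protein with ~20 sites per molecule), the usual
"free ≈ total ligand" approximation fails; the model instead treats *n*
identical, independent sites and solves the mass-action balance exactly,
giving the quadratic closed form evaluated by `bindingIntensity()`:

$$I = I_0 - \frac{I_0 - I_\infty}{2 n [P]_0}\left[\tfrac1K + [L]_0 +
n[P]_0 - \sqrt{\left(\tfrac1K + [L]_0 + n[P]_0\right)^2 -
4 n [L]_0 [P]_0}\right]$$

Intensity interpolates linearly between $I_0$ (no ligand) and $I_\infty$
(all sites filled) with the fraction of occupied sites. The discriminant
is clamped at zero before the square root — a pure floating-point guard at
the stoichiometric-equivalence point, where the exact discriminant
vanishes.

**Independent oracle.** `equilibriumIntensity()` computes the same
quantity by a different route: bisection for the free-ligand concentration
in $L + SKL/(1+KL) = [L]_0$ over the site pool $S = n[P]_0$, then the same
linear intensity map. The two routes agree to better than $10^{-9}$
relative across parameter sweeps; this equivalence is asserted in the test
suite and protects the closed form against algebra and sign errors.

**Fitting.** `fitBinding()` minimizes unweighted squared residuals
(no weighting is assumed because replicate variances are not part of the
data model). The objective has local minima — the knee position trades off
against curvature — so a deterministic multi-start is used: a 5×5 grid
over $n \in \{5, 15, 25, 50, 100\}$ and $K \in \{10^3 \dots 10^7\}$
(log-spaced), plus one data-driven start, each refined by bounded
Levenberg–Marquardt ($n \in [0.5, 200]$, $K \in [10^2, 10^9]$ M⁻¹). Two
reparameterizations improve conditioning and guarantee validity:
$K$ enters as $\log_{10} K$, and $I_\infty = q I_0$ with $q \in [0,1]$,
so $I_0 \ge I_\infty \ge 0$ holds at any bounded optimum. $I_0$ is fitted
by default (initialized at the lowest-ligand intensity) and can be fixed
with `fixI0 = TRUE` when the zero-ligand intensity was measured directly;
both modes are provided because either is defensible experimental
practice. Standard errors for $n$ and $K$ are asymptotic, from the local
curvature at the optimum ($K$ by the delta method); no bootstrap is run by
default. When the titration never reaches the fitted site capacity
($\max[L]_0 < \hat n [P]_0$) the fit carries an identifiability warning:
without a saturating tail, $n$ and $K$ are only weakly determined.

```{r binding}
fit <- fitBinding(simulateTitration(noiseSd = 0.01, seed = 1))
fit
```

## The FRET spectroscopic ruler

Energy transfer from the protein's tryptophans (donor) to the bound
polyphenol (acceptor) reports their separation over roughly 2–8 nm. The
chain is: overlap integral → Förster radius → efficiency → distance.

The overlap integral
$J = \int F(\lambda)\varepsilon(\lambda)\lambda^4 d\lambda /
\int F(\lambda) d\lambda$
is evaluated by the trapezoidal rule on the union of the two wavelength
grids with linear interpolation and zero extension outside each spectrum's
support (`overlapIntegral()`). Trapezoid-on-union-grid was chosen because
it is deterministic, order-independent and convergence-testable: the suite
checks agreement with a 0.001 nm brute-force grid to $10^{-4}$ relative.
The donor normalization uses the donor's full emission integral, making
$J$ invariant to donor amplitude and linear in acceptor absorptivity. The
native unit is M⁻¹cm⁻¹nm⁴; `jToCm3()` converts to cm³M⁻¹ (×10⁻²⁸) for
reporting.

The Förster radius $R_0$ (the separation at 50% transfer) uses tryptophan
defaults $\kappa^2 = 2/3$ (isotropic orientations), $\Phi = 0.118$, and
refractive index 1.366. Two prefactor conventions are exposed because
published forms of the $R_0^6$ equation disagree in their units, and the
worked literature values for this system are not mutually consistent
(the printed $J$, prefactor and $R_0$ cannot all be reproduced from one
another; under the standard Å⁶ convention the same $J$ gives
$R_0 \approx 2.36$ nm, under a literal reading of the printed constant
$\approx 5.09$ nm). `"standard_A6"` is the default; `"paper_literal"`
reproduces the printed constant verbatim. Only the efficiency–distance
relation, which is internally consistent, is treated as ground truth:

$$E = 1 - F/F_0 = \frac{R_0^6}{R_0^6 + r^6}$$

```{r fret}
distanceFromEfficiency(E = 0.69, R0 = 3.53)  # nm
100 * efficiencyFromDistance(r = 3.09, R0 = 3.53)  # %
```

`fretValidity()` applies the two acceptance criteria with strict
inequalities, $r < 7$ nm and $0.5R_0 < r < 2R_0$, as printed.

## Peak shifts

Emission and synchronous-scan maxima are located by global argmax
(`findPeak()`), optionally after Savitzky–Golay smoothing (order-2 local
polynomial; default off, since noiseless maxima need none). No band-shape
fitting is attempted because only maximum positions are interpreted. Ties
break toward the lowest wavelength — deterministic and order-independent —
and an all-flat spectrum is an error unless ties are explicitly allowed.
`peakShift()` is signed: positive means red shift, i.e. a more hydrophilic
fluorophore microenvironment.

## Ferrozine iron-release kinetics

Released Fe²⁺ complexes ferrozine; the complex absorbs at 562 nm with
$\varepsilon_{562} = 27.9$ mM⁻¹cm⁻¹, so
`concFromAbsorbance()` converts A562 to micromolar iron by Beer–Lambert.
Progress curves are fitted with a cubic polynomial on the concentration
scale (`fitCubic()`); since the curve is fitted after the linear
Beer–Lambert map, fitting before or after conversion gives identically
scaled coefficients. The initial release rate is the tangent at zero,
$v_0 = A_1$, reported in nM/min and never clamped (a negative fitted rate
is flagged instead).

A limitation worth knowing: the cubic tracks the initial tangent well only
while the trace is mildly curved. The suite verifies $v_0$ within ~4% of
truth for a saturating-exponential trace with $kT = 2$ over the 60-min
window, but for a strongly saturated trace ($kT \approx 5$, plateau
reached early) the cubic's $v_0$ underestimates the true tangent by ~25%;
the suite freezes that deterministic value rather than pretending the
approximation holds. Initial rates from strongly saturated traces should
be read as the cubic's tangent, not the mechanistic rate.

"Released iron at 60 min" is the last measured concentration, not the
fitted cubic evaluated at 60 — matching how measured amounts are reported.
`percentInhibition()` is plain arithmetic,
$100(\text{baseline}-\text{treated})/\text{baseline}$, stored exactly and
rounded to 2 decimals (round-half-even) only in reports; the tolerance of
±0.01 percentage points in the checks absorbs rounding-mode differences.

The calibration check — that protein and buffer do not perturb the
ferrozine readout — is operationalized as a slope/intercept equivalence
rule (`curvesEquivalent()`: slopes within 5% relative, intercepts within
5% of full-scale signal) rather than a named hypothesis test, because no
test is specified by the data model and an equivalence rule is
deterministic and interpretable.

```{r kinetics}
fitCubic(simulateKineticTrace("cubic", c(0.1, 0.09986, -0.001, 5e-6),
                              times = seq(0, 60, 5)))
percentInhibition(1.16, 0.16)
```

## Synthetic data: what it emulates, and what it does not

All inputs the pipeline consumes can be generated with fixed seeds:

* `simulateTitration()` — the closed-form isotherm plus additive Gaussian
  noise. Defaults are the study conditions: 1.0 µM protein, total ligand
  0–50 µM in 1 µM steps, truth $I_0 = 100$, $I_\infty = 20$, $n = 22.11$,
  $K = 4.99\times10^5$ M⁻¹.
* `simulateSpectrumPair()` — donor emission and acceptor absorption as
  Gaussian bands (donor centered 327 nm, the unbound protein's maximum);
  acceptor noise is truncated at zero since absorptivity cannot be
  negative.
* `simulateKineticTrace()` — cubic truth (matching the fitted form
  exactly) or a saturating exponential $Y_\max(1 - e^{-kt})$ for realism,
  over 0–60 min.
* `simulateStandardCurve()` — a calibration line whose default slope,
  0.0279 A562 per µM, is the Beer–Lambert value of the iron–ferrozine
  complex, so noise-free series round-trip exactly through
  `concFromAbsorbance()`.

Noise is additive Gaussian only, with its standard deviation expressed as
a fraction of the signal amplitude (scale-free); 1% is a realistic
photon-noise level for a benchtop fluorometer at these intensities. A
single integer seed drives a separate substream per generator family, so
the order in which generators are called never changes any output, and
each generator restores the caller's RNG state.

What the generators do **not** emulate: inner-filter attenuation at high
ligand absorbance, photobleaching, instrument drift, correlated baseline
noise, and scattering artifacts. Passing recovery tests on this synthetic
data therefore demonstrates the estimators are correct for the stated
model; it does not certify robustness to those instrument effects on real
scans.

## Numerical choices and degenerate inputs

* Bisection tolerance for the equilibrium oracle:
  $|f| < 10^{-14}[L]_0 + 10^{-20}$, at most 200 halvings — machine
  precision for any sane concentrations, with non-convergence an error
  rather than a silent result.
* Multi-start least squares runs with `ftol = ptol = 1e-15` so noiseless
  self-consistency recoveries hit $10^{-6}$ relative or better.
* CSV dialect is fixed (header, comma, `.` decimal, 17 significant digits
  on write) so write/read round trips are bit-faithful and parse errors
  name the offending line.
* Degenerate inputs error early with specific messages: constant
  titrations ("no quenching signal"), flat spectra ("no unique peak"),
  rank-deficient kinetic designs, sub-minimal calibration sets.

## Problem sizes in the checks

The suite's stochastic checks use 50 replicate titrations (51 points
each) for parameter recovery, 100 replicates for the $v_0$ unbiasedness
check, 1000 for the generator-mean CLT check, and a 20×20 sweep for the
oracle equivalence — sizes chosen so each property is tested with
comfortable statistical margin while the whole suite stays quick to run
interactively.
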