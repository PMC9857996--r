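# specbind

Spectroscopic analysis of protein–ligand binding, FRET distances, and
iron-release kinetics.

Polyphenols in foodstuffs induce iron release from ferritin, which
degrades food quality (off-flavors, discoloration, Fenton chemistry). One
mitigation is a protein that sequesters the polyphenol — e.g. barley-malt
protein Z binding ferulic acid. Characterizing such an interaction, and
its effect on iron release, rests on a standard chain of steady-state
measurements. specbind implements that chain as tested, reusable R
functions for biophysicists and food chemists:

* **Binding** — a ligand-depletion fluorescence-quenching isotherm. With
  *n* identical independent sites per protein and exact mass-action
  bookkeeping of free vs. total ligand,

  *I* = *I*₀ − (*I*₀ − *I*∞)/(2*n*[P]₀) · [1/*K* + [L]₀ + *n*[P]₀ −
  √((1/*K* + [L]₀ + *n*[P]₀)² − 4*n*[L]₀[P]₀)],

  fitted by bounded multi-start Levenberg–Marquardt (`fitBinding()`),
  with a bisection equilibrium oracle as an independent cross-check.
* **FRET spectroscopic ruler** — overlap integral
  *J* = ∫*F*(λ)ε(λ)λ⁴dλ / ∫*F*(λ)dλ, Förster radius *R*₀, efficiency
  *E* = 1 − *F*/*F*₀ = *R*₀⁶/(*R*₀⁶ + *r*⁶), donor–acceptor distance
  *r*, and the validity checks *r* < 7 nm and 0.5*R*₀ < *r* < 2*R*₀
  (`fretChain()`).
* **Peak shifts** — emission/synchronous-scan maxima and signed red
  shifts (`findPeak()`, `peakShift()`).
* **Iron-release kinetics** — Beer–Lambert conversion of ferrozine A562
  (ε₅₆₂ = 27.9 mM⁻¹cm⁻¹), cubic progress-curve fits
  *Y* = *A*₀ + *A*₁*t* + *A*₂*t*² + *A*₃*t*³ with initial rate
  *v*₀ = *A*₁, percent inhibition, and FeSO₄ calibration equivalence
  (`fitCubic()`, `percentInhibition()`, `fitStandardCurve()`).
* **Synthetic data** — seeded generators for every input
  (`simulateTitration()`, `simulateSpectrumPair()`,
  `simulateKineticTrace()`, `simulateStandardCurve()`), so the whole
  pipeline is testable without instrument files.
* **Report runner** — `runReport()` chains the stages from one YAML
  config into a deterministic JSON summary; a thin CLI wrapper lives in
  `inst/scripts/pipeline.R`.

## Worked example

Fit a noisy synthetic titration generated at the study conditions
(1.0 µM protein, ligand 0–50 µM, truth n = 22.11, K = 4.99×10⁵ M⁻¹,
1% noise):

```r
library(specbind)
fitBinding(simulateTitration(noiseSd = 0.01, seed = 1))
#> Ligand-depletion quenching fit
#>   n = 21.47 +/- 0.648 sites per protein
#>   K = 4.264e+05 +/- 6.38e+04 M^-1
#>   I0 = 100.7, Iinf = 19.11, rss = 54.83 (26 starts)
```

One noisy replicate recovers n within ~3% and K within ~15% of the
generating truth; averaging 50 replicates (as the acceptance script does)
recovers n to well within 1%.

The FRET ruler on a synthetic donor/acceptor band pair, with the measured
69% quenching:

```r
pair <- simulateSpectrumPair()
fretChain(pair$donor, pair$acceptor, f = 31, f0 = 100)
#> FRET spectroscopic ruler
#>   J  = 1.327e+14 M^-1 cm^-1 nm^4 (= 1.327e-14 cm^3 M^-1)
#>   R0 = 2.532 nm (standard_A6)
#>   E  = 0.69, r = 2.216 nm
#>   r < 7 nm: TRUE; 0.5 R0 < r < 2 R0: TRUE
```

Here J is the donor–acceptor spectral overlap, R0 the distance at 50%
transfer, and r the inferred tryptophan–ligand separation; both validity
flags hold, so the distance is inside the ruler's reliable range.

Percent inhibition of iron release from the measured 60-min amounts:

```r
percentInhibition(1.16, 0.16)
#> Iron release: 1.16 uM -> 0.16 uM, decrease 86.21%
```

A full end-to-end run from the shipped demo config (synthetic fixtures in
`inst/extdata/`):

```r
cfg <- system.file("extdata", "config_demo.yaml", package = "specbind")
summary <- runReport(cfg, outDir = "out")   # writes out/report.json
```

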