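test_that("Beer-Lambert conversion is linear in A and inverse in path", {
  expect_identical(concFromAbsorbance(0), 0)
  expect_equal(concFromAbsorbance(0.0279), 1)  # 1000 * 0.0279 / 27.9
  a <- c(0.1, 0.2, 0.5)
  expect_equal(concFromAbsorbance(2 * a), 2 * concFromAbsorbance(a))
  expect_equal(concFromAbsorbance(0.1, pathLength = 0.5),
               2 * concFromAbsorbance(0.1, pathLength = 1))
  expect_error(concFromAbsorbance(-0.1), "non-negative")
})

test_that("asConcentration converts absorbance traces once", {
  tr <- KineticTrace(0:10, seq(0, 0.0279, length.out = 11),
                     valueKind = "absorbance")
  conc <- asConcentration(tr)
  expect_identical(conc@valueKind, "concentration")
  expect_equal(conc@values[11], 1)
  expect_identical(asConcentration(conc), conc)
})

test_that("cubic fits reproduce a generating cubic exactly", {
  truth <- c(0.1, 0.09986, -0.001, 5e-6)
  tr <- simulateKineticTrace("cubic", truth, times = seq(0, 60, 5),
                             noiseSd = 0)
  fit <- fitCubic(tr)
  expect_equal(unname(fit@coefficients), truth, tolerance = 1e-9)
  expect_equal(initialRate(fit), 99.86, tolerance = 1e-9)
  expect_lt(fit@rss, 1e-20)
})

test_that("nested models collapse to the right coefficients", {
  line <- KineticTrace(seq(0, 60, 5), 2 + 0.05 * seq(0, 60, 5))
  fl <- fitCubic(line)
  expect_equal(unname(fl@coefficients), c(2, 0.05, 0, 0), tolerance = 1e-9)
  expect_equal(initialRate(fl), 50, tolerance = 1e-9)

  const <- KineticTrace(seq(0, 60, 5), rep(1.2, 13))
  expect_equal(initialRate(fitCubic(const)), 0, tolerance = 1e-9)
})

test_that("degenerate kinetic designs are rejected", {
  expect_error(fitCubic(KineticTrace(c(0, 1, 2, 3), c(0, 1, 2, 3))),
               "at least 5")
  expect_error(
    fitCubic(KineticTrace(0:10, rep(0.1, 11), valueKind = "absorbance")),
    "asConcentration")
  expect_error(KineticTrace(c(0, 1, 1, 2, 3), 1:5), "strictly increasing")
})

test_that("a negative initial rate is flagged, not clamped", {
  tr <- simulateKineticTrace("cubic", c(1, -0.01, 0, 0),
                             times = seq(0, 60, 5), noiseSd = 0)
  fit <- fitCubic(tr)
  expect_lt(initialRate(fit), 0)
  expect_match(fitWarnings(fit), "negative", all = FALSE)
})

test_that("v0 is unbiased on noisy cubics (mean within 2 SE over seeds)", {
  truth <- c(0.1, 0.09986, -0.001, 5e-6)
  v0 <- vapply(1:100, function(i) {
    tr <- simulateKineticTrace("cubic", truth, times = seq(0, 60, 2.5),
                               noiseSd = 0.02, seed = 9000 + i)
    initialRate(fitCubic(tr))
  }, numeric(1))
  se <- stats::sd(v0) / sqrt(length(v0))
  expect_lt(abs(mean(v0) - 99.86), 2 * se + 1e-9)
})

test_that("percent inhibition reproduces the printed 60-min decreases", {
  cases <- list(c(0.16, 86.21), c(0.67, 42.24), c(0.82, 29.31))
  for (cs in cases) {
    r <- percentInhibition(1.16, cs[1])
    expect_equal(round(r@percentDecrease, 2), cs[2], tolerance = 1e-9)
  }
  expect_equal(percentInhibition(0.7, 0.7)@percentDecrease, 0)
  expect_equal(percentInhibition(0.7, 0)@percentDecrease, 100)
  # monotone decreasing in the treated amount
  pd <- vapply(seq(0, 1.16, 0.1), function(tr)
    percentInhibition(1.16, tr)@percentDecrease, numeric(1))
  expect_true(all(diff(pd) < 0))
  expect_error(percentInhibition(0, 0.1), "positive")
})

test_that("the ferrozine standard curve fits and round-trips Beer-Lambert", {
  pts <- simulateStandardCurve(noiseSd = 0)
  crv <- fitStandardCurve(pts$conc_uM, pts$a562)
  expect_equal(crv@slope, 0.0279, tolerance = 1e-9)
  expect_equal(crv@intercept, 0, tolerance = 1e-12)
  expect_equal(crv@r2, 1)
  # the slope is the Beer-Lambert coefficient: A -> conc recovers the grid
  expect_equal(concFromAbsorbance(pts$a562), pts$conc_uM, tolerance = 1e-9)

  noisy <- simulateStandardCurve(noiseSd = 0.001 / (0.0279 * 50), seed = 4)
  expect_gt(fitStandardCurve(noisy$conc_uM, noisy$a562)@r2, 0.99)

  expect_error(fitStandardCurve(c(10, 20), c(0.3, 0.6)), "at least 3")
  expect_error(fitStandardCurve(rep(10, 4), c(0.3, 0.3, 0.3, 0.3)),
               "zero variance")
})

test_that("calibration equivalence applies the slope/intercept rule", {
  a <- fitStandardCurve(c(10, 30, 50), 0.0279 * c(10, 30, 50))
  expect_true(curvesEquivalent(a, a))
  b10 <- fitStandardCurve(c(10, 30, 50), 1.10 * 0.0279 * c(10, 30, 50))
  expect_false(curvesEquivalent(a, b10))
  b3 <- fitStandardCurve(c(10, 30, 50), 1.03 * 0.0279 * c(10, 30, 50) +
                           0.0279 * 50 * 0.04 * c(-1, 0, 1) * 0)
  expect_true(curvesEquivalent(a, b3))
})

test_that("finalRelease reads the last measured concentration", {
  tr <- simulateKineticTrace("saturating_exponential", c(1.16, 0.0861),
                             noiseSd = 0)
  expect_identical(finalRelease(tr), tr@values[length(tr)])
  j <- jsonlite::fromJSON(kineticsJSON(percentInhibition(1.16, 0.16)))
  expect_equal(j$percent_decrease, 86.21)
})
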