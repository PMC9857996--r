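test_that("transfer efficiency from donor quenching is 1 - F/F0", {
  expect_equal(fretEfficiency(31, 100), 0.69)
  expect_identical(fretEfficiency(100, 100), 0)
  expect_identical(fretEfficiency(0, 100), 1)
  expect_error(fretEfficiency(101, 100), "negative efficiency")
  expect_error(fretEfficiency(1, 0), "positive")
})

test_that("flat-band overlap integral matches the closed form", {
  grid <- 300:310
  donor <- Spectrum(grid, rep(1, 11), "emission")
  acceptor <- Spectrum(grid, rep(1000, 11), "absorption")
  closed <- 1000 * (310^5 - 300^5) / (5 * 10)  # 1000 * mean of lambda^4
  expect_equal(overlapIntegral(donor, acceptor), closed, tolerance = 1e-4)
})

test_that("disjoint spectra give J = 0 with a warning", {
  donor <- Spectrum(300:310, rep(1, 11), "emission")
  acceptor <- Spectrum(400:410, rep(1000, 11), "absorption")
  expect_warning(J <- overlapIntegral(donor, acceptor), "do not overlap")
  expect_identical(J, 0)
})

test_that("trapezoid J converges to the fine-grid brute-force value", {
  # independent oracle: analytic Gaussian bands evaluated on a 0.001 nm
  # grid, integrated by direct trapezoid sums
  dC <- 327; dW <- 22; aC <- 322; aW <- 28; eMax <- 15000
  fine <- seq(250, 500, by = 0.001)
  Ff <- exp(-(fine - dC)^2 / (2 * dW^2))
  ef <- eMax * exp(-(fine - aC)^2 / (2 * aW^2))
  tr <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  Joracle <- tr(fine, Ff * ef * fine^4) / tr(fine, Ff)

  pair <- simulateSpectrumPair(donorCenter = dC, donorWidth = dW,
                               donorAmp = 100, acceptorCenter = aC,
                               acceptorWidth = aW, acceptorEpsMax = eMax,
                               noiseSd = 0)
  expect_equal(overlapIntegral(pair$donor, pair$acceptor), Joracle,
               tolerance = 1e-4)
})

test_that("J is invariant to donor scaling and linear in acceptor scaling", {
  pair <- simulateSpectrumPair(noiseSd = 0)
  J <- overlapIntegral(pair$donor, pair$acceptor)
  d7 <- Spectrum(wavelengths(pair$donor), 7 * spectrumValues(pair$donor),
                 "emission")
  a3 <- Spectrum(wavelengths(pair$acceptor),
                 3 * spectrumValues(pair$acceptor), "absorption")
  expect_equal(overlapIntegral(d7, pair$acceptor), J, tolerance = 1e-12)
  expect_equal(overlapIntegral(pair$donor, a3), 3 * J, tolerance = 1e-12)
})

test_that("Forster radius follows sixth-root scaling in both conventions", {
  expect_identical(forsterRadius(0), 0)
  for (conv in c("standard_A6", "paper_literal")) {
    const <- FretConstants(convention = conv)
    J <- if (conv == "standard_A6") 8.74e13 else 8.74e-15
    expect_equal(forsterRadius(64 * J, const), 2 * forsterRadius(J, const),
                 tolerance = 1e-12)
  }
  # independent sixth-root arithmetic for the standard convention
  J <- 8.74e13  # M^-1 cm^-1 nm^4, i.e. 8.74e-15 cm^3 M^-1
  expected <- (8.79e-5 * (2 / 3) * 1.366^(-4) * 0.118 * J)^(1 / 6) / 10
  expect_equal(forsterRadius(J), expected, tolerance = 1e-12)
  expect_equal(forsterRadius(J), 2.36, tolerance = 0.005)
  expect_equal(jToCm3(J), 8.74e-15)
})

test_that("distance and efficiency reproduce the tryptophan-donor chain", {
  expect_equal(distanceFromEfficiency(0.69, 3.53), 3.09, tolerance = 0.005 / 3.09)
  expect_equal(efficiencyFromDistance(3.09, 3.53), 0.69, tolerance = 0.005 / 0.69)
  expect_equal(distanceFromEfficiency(0.5, 3.53), 3.53)
  expect_equal(distanceFromEfficiency(1 / 65, 3.53), 2 * 3.53)
  expect_equal(efficiencyFromDistance(3.53, 3.53), 0.5)
  expect_identical(efficiencyFromDistance(0, 3.53), 1)
  expect_error(distanceFromEfficiency(0, 3.53), "strictly between")
  expect_error(distanceFromEfficiency(1, 3.53), "strictly between")
})

test_that("distance/efficiency are mutual inverses and strictly monotone", {
  E <- seq(0.01, 0.99, by = 0.01)
  r <- vapply(E, distanceFromEfficiency, numeric(1), R0 = 3.53)
  back <- vapply(r, efficiencyFromDistance, numeric(1), R0 = 3.53)
  expect_equal(back, E, tolerance = 1e-12)
  expect_true(all(diff(r) < 0))           # r strictly decreasing in E
  rr <- seq(0.5, 10, by = 0.1)
  expect_true(all(diff(efficiencyFromDistance(rr, 3.53)) < 0))
})

test_that("validity flags apply the printed criteria strictly", {
  f <- fretValidity(3.09, 3.53)
  expect_true(f$validDistance && f$validRange)
  expect_false(fretValidity(8, 3.53)$validDistance)
  expect_false(fretValidity(0.5 * 3.53, 3.53)$validRange)  # boundary strict
  expect_false(fretValidity(2 * 3.53, 3.53)$validRange)
})

test_that("fretChain threads the full ruler consistently", {
  pair <- simulateSpectrumPair(noiseSd = 0)
  res <- fretChain(pair$donor, pair$acceptor, f = 31, f0 = 100)
  expect_s4_class(res, "FretResult")
  expect_equal(res@E, 0.69)
  expect_equal(res@J, overlapIntegral(pair$donor, pair$acceptor))
  expect_equal(res@Jcm3, res@J * 1e-28)
  expect_equal(res@R0, forsterRadius(res@J))
  expect_equal(res@r, distanceFromEfficiency(0.69, res@R0))
  j <- jsonlite::fromJSON(fretResultJSON(res))
  expect_equal(j$r_nm, res@r)
  expect_identical(j$convention, "standard_A6")
})
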