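test_that("response FWHM follows the noise + Fano closed form", {
  calNoise <- instrumentCalibration(5, 1e10, noiseFWHM = 80, fano = 0)
  expect_equal(responseProfile(3, calNoise)$fwhm, 80 / 1000)

  calFano <- instrumentCalibration(5, 1e10, noiseFWHM = 0, fano = 0.114)
  expect_equal(responseProfile(4, calFano)$fwhm,
               sqrt(2) * responseProfile(2, calFano)$fwhm)

  # hand evaluation: sqrt(60^2 + 2.355^2 * 0.114 * 3.65 * 2308) = 94.478 eV
  cal <- instrumentCalibration(5, 1e10, noiseFWHM = 60, fano = 0.114,
                               wEH = 3.65)
  expect_equal(responseProfile(2.308, cal)$fwhm, 0.094478, tolerance = 1e-4)
})

test_that("a zero-count spectrum yields zero rates", {
  cal <- testCalib()
  spec <- sddSpectrum(rep(0, 550), 0.7, 0.01, 5)
  fit <- fitSpectrum(spec, c("S", "K"), cal)
  expect_equal(fit$rate, c(0, 0))
  expect_true(all(fit$converged))
})

test_that("a single noisy Gaussian line is recovered within 3 uncertainties", {
  cal <- testCalib()
  A <- 5000
  spec <- composeSpectrum(A, 2.308, cal, background = 2, poissonSeed = 42)
  fit <- fitSpectrum(spec, "S", cal)
  expect_true(fit$converged)
  expect_lt(abs(fit$rate - A / 5), 3 * fit$rateSE)
})

test_that("overlapping lines 150 eV apart are separated exactly without noise", {
  cal <- testCalib()
  l1 <- makeLine(2.0); l2 <- makeLine(2.15, element = "Y")
  spec <- composeSpectrum(c(2000, 1000), c(2.0, 2.15), cal, background = 1)
  fit <- fitSpectrum(spec, list(l1, l2), cal)
  expect_equal(fit$rate[1], 2000 / 5, tolerance = 1e-3)
  expect_equal(fit$rate[2], 1000 / 5, tolerance = 1e-3)
  expect_lt(abs(fit$rate[1] / fit$rate[2] - 2), 2e-3)
})

test_that("the fitted model conserves counts on noiseless input", {
  cal <- testCalib()
  areas <- c(3000, 1500)
  spec <- composeSpectrum(areas, c(2.0, 2.15), cal, background = 0)
  fit <- fitSpectrum(spec, list(makeLine(2.0), makeLine(2.15, "Y")), cal,
                     backgroundOrder = 0)
  expect_equal(sum(fit$rate) * 5, sum(areas), tolerance = 1e-3)
})

test_that("a constant background offset leaves the fitted rates unchanged", {
  cal <- testCalib()
  base <- composeSpectrum(4000, 2.308, cal, background = 0)
  shifted <- sddSpectrum(spectrumCounts(base) + 25, 0.7, 0.01, 5)
  f1 <- fitSpectrum(base, "S", cal)
  f2 <- fitSpectrum(shifted, "S", cal)
  expect_equal(f2$rate, f1$rate, tolerance = 1e-6)
})

test_that("1-sigma intervals achieve Poisson coverage between 60 and 75 percent", {
  cal <- testCalib()
  A <- 3000
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    spec <- composeSpectrum(A, 2.308, cal, background = 2, poissonSeed = 1000 + i)
    fit <- fitSpectrum(spec, "S", cal)
    if (abs(fit$rate - A / 5) <= fit$rateSE) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.60)
  expect_lte(hits / reps, 0.75)
})

test_that("degenerate windows and out-of-range lines are rejected", {
  cal <- testCalib()
  tiny <- sddSpectrum(c(1, 2), 2.305, 0.005, 1)
  expect_error(fitSpectrum(tiny, "S", cal), "degenerate fit window")
  spec <- sddSpectrum(rep(1, 100), 0.7, 0.01, 1) # tops out at 1.69 keV
  expect_error(fitSpectrum(spec, "S", cal), "inside the spectrum")
})

test_that("absolute intensity normalization follows the identity and scaling laws", {
  idCal <- instrumentCalibration(5, flux = 1, efficiency = 1,
                                 solidAngle = 4 * pi, thetaIn = 90)
  expect_equal(absoluteIntensity(123, 2.308, idCal), 123)

  cal1 <- instrumentCalibration(5, 1e10, solidAngle = 0.2)
  cal2 <- instrumentCalibration(5, 1e10, solidAngle = 0.1)
  expect_equal(absoluteIntensity(50, 2.308, cal2),
               2 * absoluteIntensity(50, 2.308, cal1))

  # hand-evaluated quotient: 500 / (sin45 * 1e10 * 0.8 * 1e-3)
  cal <- instrumentCalibration(5, flux = 1e10, efficiency = 0.8,
                               solidAngle = 4 * pi * 1e-3, thetaIn = 45)
  expect_equal(absoluteIntensity(500, 2.308, cal), 8.8388348e-5,
               tolerance = 1e-7)
})

test_that("spectrum text files round-trip integer counts bit-exactly", {
  set.seed(7)
  counts <- rpois(300, 40)
  spec <- sddSpectrum(counts, offset = 0.65, gain = 0.012, liveTime = 3.5)
  path <- tempfile(fileext = ".txt")
  writeSpectrum(spec, path)
  back <- readSpectrum(path)
  expect_identical(spectrumCounts(back), as.numeric(counts))
  expect_equal(back@offset, 0.65)
  expect_equal(back@gain, 0.012)
  expect_equal(liveTime(back), 3.5)
})
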