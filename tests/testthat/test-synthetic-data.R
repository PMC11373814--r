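test_that("zero heterogeneity produces constant fields at the medians", {
  prof <- conditionProfile("PC", sigma = 0)
  truth <- simulateMap(prof, 4, 3, seed = 1, thicknessSigma = 0)
  for (el in elements(truth))
    expect_true(all(concentrations(truth, el) == prof@medians[[el]]))
  expect_true(all(thicknessField(truth) == prof@thicknessMedian))
})

test_that("generators are pure functions of parameters and seed", {
  prof <- conditionProfile("6Gy-D3")
  t1 <- simulateMap(prof, 6, 5, seed = 7)
  t2 <- simulateMap(prof, 6, 5, seed = 7)
  expect_identical(t1@fields, t2@fields)
  expect_identical(t1@thickness, t2@thickness)
  t3 <- simulateMap(prof, 6, 5, seed = 8)
  expect_false(identical(t1@fields, t3@fields))

  e1 <- simulateFtir("PC", 3, seed = 9)
  e2 <- simulateFtir("PC", 3, seed = 9)
  expect_identical(lapply(e1, absorbance), lapply(e2, absorbance))

  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateMap(prof, 3, 3, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("large-grid sample medians sit on the lognormal scale parameter", {
  prof <- conditionProfile("HP")
  truth <- simulateMap(prof, 100, 100, seed = 13)
  for (el in elements(truth)) {
    m <- median(concentrations(truth, el))
    expect_equal(m, prof@medians[[el]], tolerance = 0.02,
                 label = paste("median", el))
  }
})

test_that("treated-condition Cl fields anti-correlate with P and K", {
  prof <- conditionProfile("2Gy-D3") # anti-correlation on by default
  truth <- simulateMap(prof, 40, 40, seed = 17)
  cl <- log(as.numeric(concentrations(truth, "Cl")))
  p <- log(as.numeric(concentrations(truth, "P")))
  k <- log(as.numeric(concentrations(truth, "K")))
  expect_lt(cor(cl, p), -0.1)
  expect_lt(cor(cl, k), -0.1)

  hp <- simulateMap(conditionProfile("HP"), 40, 40, seed = 17)
  expect_lt(abs(cor(log(as.numeric(concentrations(hp, "Cl"))),
                    log(as.numeric(concentrations(hp, "P"))))), 0.2)
})

test_that("the expected pixel spectrum equals a hand-composed forward model", {
  cal <- testCalib(); m <- testMatrix()
  conc <- c(P = 28.9, S = 22.9, Cl = 12.9, K = 46.3)
  d <- 1.15e-4
  got <- expectedSpectrum(conc, d, cal, m, dwell = 5,
                          substrateRate = 5000, background = 0.5)

  # independent composition straight from the quantification equation
  E <- 0.7 + 0.01 * (0:549)
  sinth <- sin(cal@thetaIn * pi / 180)
  hand <- rep(0.5, 550)
  for (el in names(conc)) {
    ln <- lineLookup(el)
    mu0 <- matrixMu(m, cal@incidentEnergy)
    mui <- matrixMu(m, ln@energy)
    x <- (mu0 + mui) * m@density * d / sinth
    A <- (1 - exp(-x)) / x
    N <- (conc[[el]] / 1000) * d * ln@fluorYield * ln@transitionProb *
      tauK(el, cal@incidentEnergy) * A * sinth * cal@flux *
      efficiencyAt(cal, ln@energy) * cal@solidAngle / (4 * pi)
    pr <- responseProfile(ln@energy, cal)
    hand <- hand + N * dnorm(E, ln@energy, pr$sigma) * 0.01
  }
  si <- lineLookup("Si")
  att <- exp(-(matrixMu(m, cal@incidentEnergy) + matrixMu(m, si@energy)) *
               m@density * d / sinth)
  prSi <- responseProfile(si@energy, cal)
  hand <- hand + 5000 * att * dnorm(E, si@energy, prSi$sigma) * 0.01
  expect_equal(got, hand * 5, tolerance = 1e-9)
})

test_that("zero concentrations leave only background and the substrate line", {
  cal <- testCalib(); m <- testMatrix()
  prof <- conditionProfile("PC", sigma = 0)
  truth <- simulateMap(prof, 1, 1, seed = 2, thicknessSigma = 0)
  truth@fields <- lapply(truth@fields, function(f) f * 0 + 1e-12)
  fwd <- forwardXrf(truth, cal, m, seed = 3, poisson = FALSE)
  spec <- fwd$spectra[[1]]
  E <- energyAxis(spec)
  y <- spectrumCounts(spec)
  # channels near the analyte lines carry only the flat background
  for (el in c("P", "S", "Cl", "K")) {
    at <- which.min(abs(E - lineLookup(el)@energy))
    expect_equal(y[at], 0.5 * 5, tolerance = 1e-3)
  }
  atSi <- which.min(abs(E - lineLookup("Si")@energy))
  expect_gt(y[atSi], 10) # the substrate line remains
})

test_that("Poisson sampling reproduces the channel expectation", {
  cal <- testCalib(); m <- testMatrix()
  prof <- conditionProfile("HP", sigma = 0)
  truth <- simulateMap(prof, 1, 1, seed = 4, thicknessSigma = 0)
  exp1 <- forwardXrf(truth, cal, m, seed = 1, poisson = FALSE)$spectra[[1]]
  ch <- which.max(spectrumCounts(exp1)) # the strongest channel
  mu <- spectrumCounts(exp1)[ch]
  draws <- vapply(1:500, function(i)
    spectrumCounts(forwardXrf(truth, cal, m, seed = 1000 + i)$spectra[[1]])[ch],
    numeric(1))
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 500))
})

test_that("noiseless FTIR generation closes through the fit to 1e-3", {
  for (label in c("PC", "HP")) {
    truth <- conditionProfile(label)@ftirRatios
    sp <- simulateFtir(label, 1, seed = 1, noise = 0, jitter = 0)[[1]]
    r <- structureRatios(fitAmideI(baselineCorrect(sp)))
    expect_equal(r[names(truth)], truth, tolerance = 1e-3)
    expect_equal(r[["amide_I_total"]], sum(truth), tolerance = 1e-3)
  }
})

test_that("the 900-spectrum ensemble mean recovers the stored ratio profile", {
  truth <- conditionProfile("PC")@ftirRatios
  ens <- simulateFtir("PC", 900, seed = 27)
  st <- fitAmideEnsemble(ens)$stats
  tot <- st$mean[st$ratio == "amide_I_total"]
  expect_equal(tot, sum(truth), tolerance = 0.02)
})

test_that("unknown condition labels are rejected", {
  expect_error(conditionProfile("XX"), "unknown condition")
  expect_error(simulateFtir("XX", 1, seed = 1), "unknown condition")
  expect_setequal(listConditions(),
                  c("HP", "PC", "2Gy-D3", "2Gy-D12", "6Gy-D3", "6Gy-D12"))
})
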