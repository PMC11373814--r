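test_that("absorption correction has the thin-film limit and known closed-form value", {
  expect_equal(absorptionCorrection(100, 200, 1.35, 0), 1)
  # x = ln 2: factor = (1 - 1/2) / ln 2
  d <- log(2) * sin(pi / 4) / (300 * 1.35)
  expect_equal(absorptionCorrection(100, 200, 1.35, d, 45),
               0.5 / log(2), tolerance = 1e-12)
})

test_that("absorption correction agrees with numerical depth integration", {
  set.seed(3)
  for (i in 1:12) {
    mu0 <- runif(1, 20, 900); mui <- runif(1, 20, 900)
    rho <- runif(1, 0.8, 2); d <- runif(1, 1e-5, 5e-4)
    theta <- runif(1, 20, 90)
    quad <- integrate(function(z)
      exp(-(mu0 + mui) * rho * z / sin(theta * pi / 180)),
      0, d, rel.tol = 1e-12)$value / d
    expect_equal(absorptionCorrection(mu0, mui, rho, d, theta), quad,
                 tolerance = 1e-8)
  }
})

test_that("absorption correction is monotone in thickness, attenuation and angle", {
  ds <- seq(1e-5, 1e-3, length.out = 20)
  A <- absorptionCorrection(100, 300, 1.35, ds, 45)
  expect_true(all(diff(A) < 0))
  mus <- seq(50, 2000, length.out = 20)
  A2 <- absorptionCorrection(mus, 0, 1.35, 2e-4, 45)
  expect_true(all(diff(A2) < 0))
  th <- seq(10, 90, length.out = 20)
  A3 <- absorptionCorrection(100, 300, 1.35, 2e-4, th)
  expect_true(all(diff(A3) > 0))
  expect_true(all(A > 0 & A <= 1))
})

test_that("zero signal quantifies to zero concentration", {
  cc <- concentration(0, 0.5, "S", testCalib(), testMatrix(), 1.5e-4)
  expect_equal(cc[["concentration"]], 0)
  expect_gte(cc[["csu"]], 0)
})

test_that("noiseless Sherman forward-inverse identity holds to 1e-6", {
  cal <- testCalib(); m <- testMatrix()
  set.seed(11)
  for (i in 1:20) {
    el <- sample(c("P", "S", "Cl", "K"), 1)
    C <- runif(1, 3, 60)            # mg/cm^3
    d <- runif(1, 0.5e-4, 4e-4)     # cm
    rate <- expectedRate(C, el, cal, m, d)
    rec <- concentration(rate, 0, el, cal, m, d)
    expect_equal(rec[["concentration"]], C, tolerance = 1e-6)
  }
})

test_that("recovered areal mass is thickness-independent in the thin-film limit", {
  cal <- testCalib(); m <- testMatrix()
  M <- 25 * 1.15e-4 # fixed areal mass, mg/cm^2
  areal <- vapply(c(1e-4, 1e-5, 1e-6), function(d) {
    rate <- expectedRate(M / d, "S", cal, m, d)
    concentration(rate, 0, "S", cal, m, d)[["concentration"]] * d
  }, numeric(1))
  expect_lt(max(abs(areal / M - 1)), 1e-3)
})

test_that("quantification rejects impossible inputs", {
  cal <- testCalib(); m <- testMatrix()
  expect_error(concentration(10, 1, "S", cal, m, 0), "must be positive")
  lowE <- instrumentCalibration(2.0, 1e10) # below the S K edge
  expect_error(concentration(10, 1, "S", lowE, m, 1e-4), "below the S K edge")
})

test_that("Lambert-Beer thickness inversion is exact and flags bad ratios", {
  cal <- testCalib(); m <- testMatrix()
  expect_equal(thicknessFromSi(100, 1e10, 100, 1e10, m, cal)$d, 0)

  dTrue <- 1.5e-4
  si <- lineLookup("Si")
  mm <- matrixMu(m, cal@incidentEnergy) + matrixMu(m, si@energy)
  att <- exp(-mm * m@density * dTrue / sin(pi / 4))
  out <- thicknessFromSi(5000 * att, 1e10, 5000, 1e10, m, cal)
  expect_true(out$valid)
  expect_equal(out$d, dTrue, tolerance = 1e-10)

  bad <- thicknessFromSi(105, 1e10, 100, 1e10, m, cal)
  expect_false(bad$valid)
  expect_true(is.na(bad$d))
  zero <- thicknessFromSi(0, 1e10, 100, 1e10, m, cal)
  expect_false(zero$valid)
})

test_that("flux normalization enters the thickness ratio", {
  cal <- testCalib(); m <- testMatrix()
  dTrue <- 2e-4
  si <- lineLookup("Si")
  mm <- matrixMu(m, cal@incidentEnergy) + matrixMu(m, si@energy)
  att <- exp(-mm * m@density * dTrue / sin(pi / 4))
  # tissue measured at half the substrate flux: rates scale accordingly
  out <- thicknessFromSi(2500 * att, 0.5e10, 5000, 1e10, m, cal)
  expect_equal(out$d, dTrue, tolerance = 1e-10)
})

test_that("a 1x1 map equals the manually composed pixel pipeline", {
  cal <- testCalib(); m <- testMatrix()
  prof <- conditionProfile("PC", sigma = 0)
  truth <- simulateMap(prof, 1, 1, seed = 4)
  fwd <- forwardXrf(truth, cal, m, seed = 5, poisson = FALSE)
  map <- quantifyMap(fwd$spectra, fwd$substrate, cal, m, nx = 1, ny = 1)

  lines <- lapply(c("P", "S", "Cl", "K", "Si"), lineLookup)
  fit <- fitSpectrum(fwd$spectra[[1]], lines, cal)
  subFit <- fitSpectrum(fwd$substrate, list(lineLookup("Si")), cal)
  th <- thicknessFromSi(fit$rate[5], cal@flux, subFit$rate[1], cal@flux, m, cal)
  manual <- concentration(fit$rate[2], fit$rateSE[2], "S", cal, m, th$d)
  expect_equal(concentrations(map, "S")[1, 1], manual[["concentration"]])
  expect_equal(thicknessField(map)[1, 1], th$d * 1e4)
})

test_that("unquantifiable pixels are masked and excluded from the summary n", {
  cal <- testCalib(); m <- testMatrix()
  prof <- conditionProfile("HP")
  truth <- simulateMap(prof, 3, 3, seed = 6)
  fwd <- forwardXrf(truth, cal, m, seed = 7)
  # two dead pixels: zero counts give zero Si intensity -> flagged invalid
  fwd$spectra[[2]] <- sddSpectrum(rep(0, 550), 0.7, 0.01, 5)
  fwd$spectra[[7]] <- sddSpectrum(rep(0, 550), 0.7, 0.01, 5)
  map <- quantifyMap(fwd$spectra, fwd$substrate, cal, m, nx = 3, ny = 3)
  expect_equal(sum(validMask(map)), 7)
  s <- mapSummary(map)
  expect_true(all(s$n == 7))
})

test_that("map summaries reduce degenerate distributions correctly", {
  mk <- function(vals) matrix(vals, nrow = 1)
  const <- new("ConcentrationMap", elements = "S",
               concentration = list(S = mk(rep(7, 5))),
               csu = list(S = mk(rep(1, 5))),
               thickness = mk(rep(1.5, 5)), valid = mk(rep(TRUE, 5)),
               pixelPitch = 0.3)
  s <- mapSummary(const)
  expect_equal(s$median[1], 7)
  expect_equal(s$mean[1], 7)
  expect_equal(s$sd[1], 0)

  odd <- new("ConcentrationMap", elements = "S",
             concentration = list(S = mk(c(1, 2, 3))),
             csu = list(S = mk(rep(0.1, 3))),
             thickness = mk(rep(1, 3)), valid = mk(rep(TRUE, 3)),
             pixelPitch = 0.3)
  expect_equal(mapSummary(odd)$median[1], 2)
})
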