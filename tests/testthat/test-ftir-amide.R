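test_that("baseline correction cancels linear trends and ignores offsets", {
  w <- seq(1400, 1800, 2)
  lin <- ftirSpectrum(w, 0.4 + 3e-4 * w)
  out <- baselineCorrect(lin)
  inw <- wavenumbers(out) >= 1480 & wavenumbers(out) <= 1720
  expect_equal(max(abs(absorbance(out)[inw])), 0, tolerance = 1e-12)

  peak <- ftirSpectrum(w, pseudoVoigt(w, 5, 1540, 30, 0) + 0.1 - 2e-4 * w)
  shifted <- ftirSpectrum(w, absorbance(peak) + 0.7)
  expect_equal(absorbance(baselineCorrect(shifted)),
               absorbance(baselineCorrect(peak)), tolerance = 1e-12)
})

test_that("a peak on a sloped baseline is recovered within 0.5 percent", {
  w <- seq(1400, 1800, 2)
  spec <- ftirSpectrum(w, pseudoVoigt(w, 5, 1540, 30, 0) + 0.05 + 4e-4 * (w - 1400))
  area <- amideIIArea(baselineCorrect(spec))
  expect_equal(area, 5, tolerance = 5e-3)
})

test_that("amide II integration is exact on a rectangle and linear in scale", {
  w <- seq(1400, 1800, 2)
  rect <- ftirSpectrum(w, as.numeric(w >= 1500 & w <= 1580))
  expect_equal(amideIIArea(rect), 80)

  spec <- ftirSpectrum(w, pseudoVoigt(w, 3, 1540, 28, 0))
  expect_equal(amideIIArea(ftirSpectrum(w, 4 * absorbance(spec))),
               4 * amideIIArea(spec), tolerance = 1e-12)
  # closed-form pseudo-Voigt (Gaussian limit) area
  expect_equal(amideIIArea(spec), 3, tolerance = 0.01)

  short <- ftirSpectrum(seq(1520, 1800, 2), rep(1, 141))
  expect_error(amideIIArea(short), "not covered")
})

test_that("pseudo-Voigt profiles integrate to their nominal analytic area", {
  x <- seq(800, 2400, 0.25)
  for (eta in c(0, 0.4, 1)) {
    y <- pseudoVoigt(x, 2.5, 1600, 24, eta)
    expect_equal(sum(diff(x) * (y[-1] + y[-length(y)]) / 2), 2.5,
                 tolerance = if (eta > 0) 0.02 else 1e-6)
  }
})

test_that("a lone alpha-helix band is attributed to alpha only", {
  w <- seq(1400, 1800, 2)
  spec <- ftirSpectrum(w, pseudoVoigt(w, 4, 1660, 24, 0))
  model <- fitAmideI(spec)
  cmp <- model@components
  alpha <- sum(cmp$area[cmp$assignment == "alpha"])
  others <- sum(cmp$area[!cmp$assignment %in% c("alpha", "amide_II")])
  expect_equal(alpha, 4, tolerance = 0.01)
  expect_lt(others, 0.01 * alpha)
})

test_that("an all-zero spectrum is rejected as having no amide signal", {
  w <- seq(1400, 1800, 2)
  expect_error(fitAmideI(ftirSpectrum(w, rep(0, length(w)))), "no amide signal")
})

test_that("group areas of a five-component mixture are recovered at 1 percent noise", {
  # recovery from scan-averaged spectra (25 co-added scans at 1 percent
  # single-scan noise), the acquisition mode hyperspectral FTIR uses
  w <- seq(1400, 1800, 1)
  centers <- c(1630, 1690, 1650, 1660, 1678)
  fwhms <- c(30, 15, 23, 25, 20)
  areas <- c(3.2, 1.1, 3.5, 4.0, 2.4)
  groups <- c("beta_s", "beta_s", "random", "alpha", "beta_t")
  clean <- rowSums(vapply(1:5, function(i)
    pseudoVoigt(w, areas[i], centers[i], fwhms[i], 0.2), numeric(length(w))))
  truthByGroup <- tapply(areas, groups, sum)

  errs <- t(vapply(1:10, function(s) {
    set.seed(300 + s)
    noisy <- replicate(25, clean + rnorm(length(w), 0, 0.01 * max(clean)))
    cmp <- fitAmideI(ftirSpectrum(w, rowMeans(noisy)))@components
    got <- vapply(names(truthByGroup), function(g)
      sum(cmp$area[cmp$assignment == g]), numeric(1))
    abs(got / truthByGroup - 1)
  }, numeric(4)))
  expect_lt(max(apply(errs, 2, median)), 0.05)
})

test_that("structure ratios satisfy the unit case and exact group closure", {
  model <- new("AmideModel",
               components = data.frame(
                 assignment = c("beta_s", "alpha", "random", "beta_t"),
                 center = c(1630, 1660, 1650, 1678), fwhm = 25, eta = 0,
                 area = c(0, 6, 0, 0)),
               amideIIArea = 6, residualNorm = 0, converged = TRUE)
  r <- structureRatios(model)
  expect_equal(r[["alpha"]], 1)
  expect_equal(r[["amide_I_total"]], 1)
  expect_equal(r[["beta_s"]] + r[["random"]] + r[["beta_t"]], 0)
  expect_equal(r[["amide_I_total"]],
               sum(r[c("beta_s", "alpha", "random", "beta_t")]))

  noA2 <- new("AmideModel", components = model@components,
              amideIIArea = NA_real_, residualNorm = 0, converged = TRUE)
  expect_error(structureRatios(noA2), "unavailable or zero")
})

test_that("ratios are invariant under rescaling of the whole spectrum", {
  spec <- simulateFtir("PC", 1, seed = 21)[[1]]
  r1 <- structureRatios(fitAmideI(baselineCorrect(spec)))
  scaled <- ftirSpectrum(wavenumbers(spec), 3.7 * absorbance(spec))
  r2 <- structureRatios(fitAmideI(baselineCorrect(scaled)))
  expect_equal(r2, r1, tolerance = 1e-6)
})

test_that("refitting the fitted curve reproduces the areas (idempotence)", {
  spec <- baselineCorrect(simulateFtir("HP", 1, seed = 22)[[1]])
  m1 <- fitAmideI(spec)
  w <- wavenumbers(spec)
  curve <- rowSums(vapply(seq_len(nrow(m1@components)), function(i) {
    cmp <- m1@components[i, ]
    pseudoVoigt(w, cmp$area, cmp$center, cmp$fwhm, cmp$eta)
  }, numeric(length(w))))
  m2 <- fitAmideI(ftirSpectrum(w, curve))
  expect_equal(m2@components$area, m1@components$area, tolerance = 1e-4)
})

test_that("ensemble statistics reduce correctly on degenerate inputs", {
  r <- c(beta_s = 1, alpha = 2, random = 3, beta_t = 4, amide_I_total = 10)
  st <- ensembleStats(list(r, r, r))
  expect_equal(st$sd, rep(0, 5))
  expect_equal(st$mean, unname(r))

  two <- ensembleStats(rbind(c(x = 1), c(x = 3)))
  expect_equal(two$mean, 2)
  expect_equal(two$sd, sqrt(2))
  expect_error(ensembleStats(list()), "empty")
})

test_that("ensemble-calibrated recovery errors stay small at 1 percent noise", {
  # median absolute relative error < 5% for group ratios above the noise
  # floor (truth >= 0.1); absolute error < 0.02 for smaller components
  for (label in c("PC", "HP", "6Gy-D12")) {
    truth <- conditionProfile(label)@ftirRatios
    ens <- simulateFtir(label, 100, seed = 30, jitter = 0, noise = 0.01)
    rs <- fitAmideEnsemble(ens)$ratios
    for (g in names(truth)) {
      if (truth[[g]] >= 0.1) {
        expect_lt(median(abs(rs[, g] / truth[[g]] - 1)), 0.05,
                  label = paste(label, g, "relative"))
      } else {
        expect_lt(median(abs(rs[, g] - truth[[g]])), 0.02,
                  label = paste(label, g, "absolute"))
      }
    }
  }
})

test_that("FTIR text and JCAMP-DX readers agree and normalise descending axes", {
  w <- seq(1800, 1400, by = -2) # descending, instrument-native
  y <- pseudoVoigt(w, 5, 1650, 30, 0.3) + 0.02
  p1 <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.10g\t%.10g", w, y), p1)
  s1 <- readFtirTable(p1)
  expect_false(is.unsorted(wavenumbers(s1)))

  p2 <- tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic amide test",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%g", w[1]), sprintf("##LASTX=%g", w[length(w)]),
    sprintf("##NPOINTS=%d", length(w)),
    "##XYDATA=(X++(Y..Y))",
    vapply(seq(1, length(w), 4), function(i) {
      j <- min(i + 3, length(w))
      paste(c(sprintf("%.6f", w[i]), sprintf("%.10g", y[i:j])), collapse = " ")
    }, character(1)),
    "##END="
  ), p2)
  s2 <- readJcamp(p2)
  expect_equal(wavenumbers(s2), wavenumbers(s1), tolerance = 1e-9)
  expect_equal(absorbance(s2), absorbance(s1), tolerance = 1e-9)

  expect_error(readJcamp(p1), "no XYDATA")
})
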