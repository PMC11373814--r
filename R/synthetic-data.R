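#' @include AllClasses.R AllGenerics.R
NULL

# run expr with a local RNG state so generators are pure functions of
# (parameters, seed) and do not disturb the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# condition table: per-element median concentrations (mg/cm^3), median
# section thickness (um) and valid-pixel counts for the six tissue
# conditions, plus the FTIR secondary-structure area ratios vs amide II.
# The four group ratios sum to the total amide I / amide II ratio.
.conditionData <- list(
  "HP" = list(medians = c(P = 28.6, S = 13.0, Cl = 9.3, K = 29.6),
              d = 1.99, n = 271L,
              ftir = c(beta_s = 0.85, alpha = 0.28, random = 0.13, beta_t = 0.16)),
  "PC" = list(medians = c(P = 28.9, S = 22.9, Cl = 12.9, K = 46.3),
              d = 1.15, n = 599L,
              ftir = c(beta_s = 0.49, alpha = 0.70, random = 0.37, beta_t = 0.36)),
  "6Gy-D12" = list(medians = c(P = 24.8, S = 19.5, Cl = 18.3, K = 42.8),
                   d = 1.6, n = 951L,
                   ftir = c(beta_s = 0.65, alpha = 0.29, random = 0.17, beta_t = 0.26)),
  "6Gy-D3" = list(medians = c(P = 21.4, S = 17.52, Cl = 13.4, K = 39.2),
                  d = 1.1, n = 306L,
                  ftir = c(beta_s = 0.49, alpha = 0.54, random = 0.09, beta_t = 0.33)),
  "2Gy-D12" = list(medians = c(P = 19.6, S = 16.3, Cl = 12.9, K = 35.8),
                   d = 1.9, n = 659L,
                   ftir = c(beta_s = 0.49, alpha = 0.63, random = 0.06, beta_t = 0.32)),
  "2Gy-D3" = list(medians = c(P = 25.8, S = 20.5, Cl = 17.4, K = 41.9),
                  d = 1.2, n = 577L,
                  ftir = c(beta_s = 0.49, alpha = 0.53, random = 0.19, beta_t = 0.35))
)

#' Condition labels known to the generator
#' @return character vector of labels
#' @export
listConditions <- function() names(.conditionData)

#' Retrieve (or customise) a condition profile
#'
#' Returns the stored [ConditionProfile-class] for one tissue condition:
#' healthy pancreas (`HP`), sham-exposed tumour (`PC`), and tumours excised
#' 3 or 12 days after 2 Gy or 6 Gy irradiation. Median concentrations,
#' thicknesses and pixel counts are the study values; the heterogeneity
#' parameters (`sigma`, `corLength`) and the Cl-vs-P/K anti-correlation
#' (enabled by default for the treated conditions, where high-Cl regions
#' co-localise with low P and K) are generator settings, not tissue claims.
#'
#' @param label condition label, see [listConditions()]
#' @param sigma lognormal shape parameter of the concentration fields
#' @param corLength spatial correlation length, pixels
#' @param antiCorrelation logical; default `TRUE` for treated conditions
#' @param antiStrength latent-factor loading in [0, 1)
#' @return a [ConditionProfile-class]
#' @export
conditionProfile <- function(label, sigma = 0.15, corLength = 3,
                             antiCorrelation = NULL, antiStrength = 0.6) {
  cd <- .conditionData[[label]]
  if (is.null(cd)) stop("unknown condition label '", label, "'")
  if (is.null(antiCorrelation))
    antiCorrelation <- !label %in% c("HP", "PC")
  new("ConditionProfile", label = label, medians = cd$medians,
      thicknessMedian = cd$d, n = cd$n, sigma = sigma,
      corLength = corLength, antiCorrelation = antiCorrelation,
      antiStrength = antiStrength, ftirRatios = cd$ftir)
}

setMethod("show", "ConditionProfile", function(object) {
  cat(sprintf("ConditionProfile '%s': n = %d pixels, d median %.2f um\n",
              object@label, object@n, object@thicknessMedian))
  cat("  medians (mg/cm^3):",
      paste(sprintf("%s %.1f", names(object@medians), object@medians),
            collapse = ", "), "\n")
  cat(sprintf("  lognormal sigma %.2f, correlation length %.1f px, anti-correlation %s\n",
              object@sigma, object@corLength,
              if (object@antiCorrelation) "on" else "off"))
})

# separable Gaussian smoothing with edge replication, then re-standardised
# to zero mean / unit sd so the lognormal scale stays the median
.smoothStandardNormal <- function(ny, nx, corLength) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (corLength > 0) {
    r <- max(1L, ceiling(3 * corLength))
    k <- stats::dnorm(-r:r, 0, corLength)
    k <- k / sum(k)
    pad <- function(m, r) {
      m <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
      m[, c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r)), drop = FALSE]
    }
    zp <- pad(z, r)
    zp <- apply(zp, 2, function(col) stats::filter(col, k, sides = 2))
    zp <- t(apply(zp, 1, function(row) stats::filter(row, k, sides = 2)))
    z <- zp[(r + 1):(r + ny), (r + 1):(r + nx), drop = FALSE]
  }
  s <- stats::sd(z)
  if (is.finite(s) && s > 0) z <- (z - mean(z)) / s else z <- z * 0
  z
}

#' Simulate ground-truth concentration and thickness fields
#'
#' Lognormal fields with the profile's medians as scale parameters,
#' spatially smoothed to the profile's correlation length. When
#' anti-correlation is enabled, a shared smoothed latent factor loads
#' positively on P and K and negatively on Cl, reproducing the reciprocal
#' co-localisation seen in treated tissue. The thickness field is lognormal
#' around the profile's median thickness. Deterministic per (profile, seed).
#'
#' @param profile a [ConditionProfile-class]
#' @param nx,ny grid dimensions (pixels)
#' @param seed integer seed
#' @param thicknessSigma lognormal shape of the thickness field
#' @return a [GroundTruth-class]
#' @export
simulateMap <- function(profile, nx, ny, seed, thicknessSigma = 0.15) {
  stopifnot(is(profile, "ConditionProfile"), nx >= 1, ny >= 1)
  med <- profile@medians
  if (any(med <= 0)) stop("medians must be positive")
  .withSeed(seed, {
    cl <- profile@corLength
    rho <- if (profile@antiCorrelation) profile@antiStrength else 0
    f <- .smoothStandardNormal(ny, nx, cl)
    loading <- c(P = rho, S = 0, Cl = -rho, K = rho)
    fields <- list()
    for (el in names(med)) {
      zi <- .smoothStandardNormal(ny, nx, cl)
      lam <- if (el %in% names(loading)) loading[[el]] else 0
      z <- sqrt(1 - lam^2) * zi + lam * f
      fields[[el]] <- med[[el]] * exp(profile@sigma * z)
    }
    zd <- .smoothStandardNormal(ny, nx, cl)
    thickness <- profile@thicknessMedian * exp(thicknessSigma * zd)
    new("GroundTruth", fields = fields, thickness = thickness,
        profile = profile, seed = as.integer(seed))
  })
}

#' @rdname elements
setMethod("elements", "GroundTruth", function(object) names(object@fields))

#' @rdname concentrations
setMethod("concentrations", "GroundTruth", function(object, element) {
  f <- object@fields[[element]]
  if (is.null(f)) stop("element not in ground truth: ", element)
  f
})

#' @rdname thicknessField
setMethod("thicknessField", "GroundTruth", function(object) object@thickness)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth '%s': %d x %d pixels, seed %d\n",
              object@profile@label, ncol(object@thickness),
              nrow(object@thickness), object@seed))
})

#' Expected (noise-free) spectrum of one pixel
#'
#' Composes the forward Sherman model for every element line with the
#' Lambert-Beer-attenuated substrate Si K-alpha line and a flat background,
#' convolved with the Gaussian detector response. Returned as expected
#' counts per channel for the given dwell.
#'
#' @param conc named per-element concentrations, mg/cm^3
#' @param d local thickness, cm
#' @param calib an [InstrumentCalibration-class]
#' @param matrix a [TissueMatrix-class]
#' @param dwell dwell (live) time, s
#' @param substrateRate Si K-alpha count rate of the bare substrate, 1/s
#' @param background flat background rate, counts/s/channel
#' @param offset,gain,nChannels energy axis definition
#' @return numeric vector of expected counts per channel
#' @export
expectedSpectrum <- function(conc, d, calib, matrix, dwell = 5,
                             substrateRate = 5000, background = 0.5,
                             offset = 0.7, gain = 0.01, nChannels = 550) {
  E <- offset + gain * (0:(nChannels - 1))
  rate <- rep(background, nChannels)
  for (el in names(conc)) {
    line <- lineLookup(el)
    N <- expectedRate(conc[[el]], line, calib, matrix, d)
    pr <- responseProfile(line@energy, calib)
    rate <- rate + N * stats::dnorm(E, pr$center, pr$sigma) * gain
  }
  si <- lineLookup("Si")
  mSi <- matrixMu(matrix, calib@incidentEnergy) + matrixMu(matrix, si@energy)
  att <- exp(-mSi * matrix@density * d / sin(calib@thetaIn * pi / 180))
  prSi <- responseProfile(si@energy, calib)
  rate <- rate + substrateRate * att * stats::dnorm(E, prSi$center, prSi$sigma) * gain
  rate * dwell
}

#' Forward-model fluorescence spectra for a ground-truth map
#'
#' Runs [expectedSpectrum()] for every pixel, applies Poisson counting noise
#' per channel, and generates the bare-substrate reference spectrum (same
#' calibration, no tissue attenuation, longer dwell). Deterministic per
#' seed.
#'
#' @param truth a [GroundTruth-class]
#' @param calib an [InstrumentCalibration-class]
#' @param matrix a [TissueMatrix-class]
#' @param dwell per-pixel dwell time, s
#' @param seed integer seed
#' @param substrateRate Si K-alpha count rate of the bare substrate, 1/s
#' @param background flat background rate, counts/s/channel
#' @param substrateDwell dwell of the substrate reference measurement, s
#' @param poisson apply Poisson noise (`FALSE` returns expected counts)
#' @param offset,gain,nChannels energy axis definition
#' @return list with `spectra` (row-major list of [SDDSpectrum-class]),
#'   `substrate` (the reference [SDDSpectrum-class]), `nx`, `ny`
#' @export
forwardXrf <- function(truth, calib, matrix, dwell = 5, seed = 1,
                       substrateRate = 5000, background = 0.5,
                       substrateDwell = 50, poisson = TRUE,
                       offset = 0.7, gain = 0.01, nChannels = 550) {
  stopifnot(is(truth, "GroundTruth"), dwell > 0)
  ny <- nrow(truth@thickness); nx <- ncol(truth@thickness)
  els <- names(truth@fields)
  .withSeed(seed, {
    spectra <- vector("list", nx * ny)
    for (p in seq_len(nx * ny)) {
      iy <- (p - 1L) %/% nx + 1L
      ix <- (p - 1L) %% nx + 1L
      conc <- vapply(els, function(el) truth@fields[[el]][iy, ix], numeric(1))
      mu <- expectedSpectrum(conc, truth@thickness[iy, ix] * 1e-4, calib,
                             matrix, dwell, substrateRate, background,
                             offset, gain, nChannels)
      counts <- if (poisson) stats::rpois(length(mu), mu) else mu
      spectra[[p]] <- sddSpectrum(counts, offset, gain, dwell)
    }
    E <- offset + gain * (0:(nChannels - 1))
    prSi <- responseProfile(lineLookup("Si")@energy, calib)
    muSub <- (background +
                substrateRate * stats::dnorm(E, prSi$center, prSi$sigma) * gain) *
      substrateDwell
    subCounts <- if (poisson) stats::rpois(length(muSub), muSub) else muSub
    list(spectra = spectra,
         substrate = sddSpectrum(subCounts, offset, gain, substrateDwell),
         nx = nx, ny = ny)
  })
}

# generator layout of the amide bands: the five amide I secondary-structure
# components plus the amide II band. Component shapes are Gaussian by
# default (eta = 0) so that the analytic component areas coincide with what
# windowed integration and the fit report; see the methods vignette.
.ftirLayout <- function(eta = 0) {
  list(
    amideI = data.frame(
      assignment = c("beta_s", "beta_s", "random", "alpha", "beta_t"),
      center = c(1630, 1690, 1650, 1660, 1678),
      fwhm = c(32, 14, 24, 24, 20),
      share = c(0.78, 0.22, 1, 1, 1), # split of the group area across bands
      eta = eta,
      stringsAsFactors = FALSE
    ),
    amideII = list(center = 1540, fwhm = 34, eta = 0)
  )
}

#' Simulate an FTIR ensemble for one condition
#'
#' Each spectrum is the amide II band (fixed pseudo-Voigt at 1540 1/cm)
#' plus the five amide I components whose areas are the condition's stored
#' ratios times the amide II area, jittered per spectrum by a lognormal
#' relative sigma, plus additive Gaussian noise and a gentle random linear
#' baseline. The windowed amide II integral is calibrated to equal the
#' nominal area, so the stored ratios are the measurement-scale ground
#' truth. Deterministic per (label, n, seed).
#'
#' @param label condition label, see [listConditions()]
#' @param n ensemble size (the reporting unit is 900 spectra per condition)
#' @param seed integer seed
#' @param noise additive noise sd relative to the peak absorbance
#' @param jitter relative lognormal sd of the per-spectrum component areas
#' @param eta Lorentzian mixing of the generated amide I components
#' @param amideIINominal nominal amide II area, AU/cm
#' @param axis wavenumber axis, 1/cm
#' @return list of [FTIRSpectrum-class] of length `n`
#' @export
simulateFtir <- function(label, n, seed, noise = 0.01, jitter = 0.03,
                         eta = 0, amideIINominal = 10,
                         axis = seq(1400, 1800, by = 2)) {
  profile <- conditionProfile(label)
  ratios <- profile@ftirRatios
  lay <- .ftirLayout(eta)
  a1 <- lay$amideI
  a2 <- lay$amideII

  # calibrate the amide II band so its trapezoidal integral over the
  # analysis window equals the nominal area (compensates tail truncation)
  probe <- ftirSpectrum(axis, pseudoVoigt(axis, 1, a2$center, a2$fwhm, a2$eta))
  a2Scale <- 1 / amideIIArea(probe)
  compArea0 <- ratios[a1$assignment] * a1$share * amideIINominal

  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      jit <- exp(stats::rnorm(nrow(a1), 0, jitter) - jitter^2 / 2)
      y <- pseudoVoigt(axis, amideIINominal * a2Scale, a2$center, a2$fwhm, a2$eta)
      for (j in seq_len(nrow(a1)))
        y <- y + pseudoVoigt(axis, compArea0[j] * jit[j],
                             a1$center[j], a1$fwhm[j], a1$eta[j])
      peak <- max(y)
      base <- stats::runif(1, 0, 0.05) +
        stats::runif(1, -1e-4, 1e-4) * (axis - 1600)
      y <- y + base + stats::rnorm(length(axis), 0, noise * peak)
      ftirSpectrum(axis, y)
    })
  })
}
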