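#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an energy-dispersive spectrum
#'
#' @param counts non-negative counts per channel
#' @param offset energy of channel 0, keV
#' @param gain channel width, keV
#' @param liveTime live time, s
#' @return an [SDDSpectrum-class]
#' @export
sddSpectrum <- function(counts, offset, gain, liveTime) {
  new("SDDSpectrum", counts = as.numeric(counts), offset = offset,
      gain = gain, liveTime = liveTime)
}

#' @rdname energyAxis
setMethod("energyAxis", "SDDSpectrum", function(object) {
  object@offset + object@gain * (seq_along(object@counts) - 1)
})

#' @rdname spectrumCounts
setMethod("spectrumCounts", "SDDSpectrum", function(object) object@counts)

#' @rdname liveTime
setMethod("liveTime", "SDDSpectrum", function(object) object@liveTime)

setMethod("show", "SDDSpectrum", function(object) {
  e <- energyAxis(object)
  cat(sprintf("SDDSpectrum: %d channels, %.3f-%.3f keV, %.0f counts, live time %g s\n",
              length(object@counts), e[1], e[length(e)],
              sum(object@counts), object@liveTime))
})

#' Construct an instrument calibration record
#'
#' @param incidentEnergy incident photon energy E0, keV
#' @param flux incident photon flux, photons/s
#' @param efficiency detector efficiency: either a single value in (0, 1]
#'   (taken as flat) or a two-column matrix (energy keV, efficiency)
#' @param solidAngle effective solid angle of detection, sr
#' @param thetaIn,thetaOut incidence and detection angles w.r.t. the sample
#'   surface, degrees
#' @param noiseFWHM electronic noise FWHM-equivalent, eV
#' @param fano Fano factor
#' @param wEH electron-hole pair creation energy of silicon, eV
#' @param relUncertainty named relative systematic uncertainty budget
#' @return an [InstrumentCalibration-class]
#' @export
instrumentCalibration <- function(incidentEnergy, flux, efficiency = 0.8,
                                  solidAngle = 0.1,
                                  thetaIn = 45, thetaOut = 45,
                                  noiseFWHM = 60, fano = 0.114, wEH = 3.65,
                                  relUncertainty = c(fp = 0.20,
                                                     efficiency = 0.05,
                                                     solidAngle = 0.04,
                                                     flux = 0.03)) {
  if (is.numeric(efficiency) && is.null(dim(efficiency))) {
    stopifnot(length(efficiency) == 1L)
    efficiency <- cbind(energy_keV = c(0.1, 50), efficiency = rep(efficiency, 2))
  }
  efficiency <- as.matrix(efficiency)
  new("InstrumentCalibration",
      incidentEnergy = incidentEnergy, flux = flux, efficiency = efficiency,
      solidAngle = solidAngle, thetaIn = thetaIn, thetaOut = thetaOut,
      noiseFWHM = noiseFWHM, fano = fano, wEH = wEH,
      relUncertainty = relUncertainty)
}

#' Default synthetic-beamline calibration
#'
#' Incident energy 5 keV (above the K edge of potassium, below the tabulated
#' range ends), flux 1e10 photons/s, flat 80% detector efficiency, 0.1 sr
#' effective solid angle, 45/45 degree geometry, and a typical SDD resolution
#' model (60 eV electronic noise, Fano factor 0.114).
#'
#' @return an [InstrumentCalibration-class]
#' @export
defaultCalibration <- function() {
  instrumentCalibration(incidentEnergy = 5.0, flux = 1e10)
}

#' Detector efficiency at an energy
#'
#' Linear interpolation of the calibration's efficiency grid (constant
#' extrapolation at the grid ends).
#'
#' @param calib an [InstrumentCalibration-class]
#' @param energy photon energy (keV), vectorized
#' @return efficiency, dimensionless in (0, 1]
#' @export
efficiencyAt <- function(calib, energy) {
  eff <- calib@efficiency
  stats::approx(eff[, 1], eff[, 2], xout = energy, rule = 2)$y
}

#' Detector response profile for a fluorescence line
#'
#' Gaussian peak centred at the line energy with
#' \deqn{FWHM^2 = noise^2 + 2.355^2 \, F \, w \, E}
#' where `F` is the Fano factor, `w` the electron-hole pair creation energy
#' of silicon and `E` the line energy (all in eV).
#'
#' @param lineEnergy line energy, keV
#' @param calib an [InstrumentCalibration-class]
#' @return list with `center` (keV), `fwhm` (keV) and `sigma` (keV)
#' @export
responseProfile <- function(lineEnergy, calib) {
  stopifnot(lineEnergy > 0)
  fwhmEV <- sqrt(calib@noiseFWHM^2 +
                 2.355^2 * calib@fano * calib@wEH * lineEnergy * 1000)
  list(center = lineEnergy, fwhm = fwhmEV / 1000,
       sigma = fwhmEV / 1000 / (2 * sqrt(2 * log(2))))
}

# resolve a lines argument: character symbols or a list of EmissionLine
.resolveLines <- function(lines) {
  if (is.character(lines)) lines <- lapply(lines, lineLookup)
  if (is(lines, "EmissionLine")) lines <- list(lines)
  stopifnot(length(lines) >= 1L,
            all(vapply(lines, is, logical(1), "EmissionLine")))
  lines
}

#' Fit fluorescence line intensities in a spectrum
#'
#' Deconvolves the spectrum into Gaussian detector-response profiles at the
#' known line energies plus a polynomial background, fitted jointly per
#' window by Poisson-weighted least squares. Fit windows extend
#' `windowFwhm` FWHM to either side of each line and are merged when they
#' overlap (overlapping lines are fitted jointly). Since the profile centres
#' and widths follow from the calibration, the line areas and background
#' coefficients enter linearly and the weighted normal equations give the
#' exact minimum together with covariance-based uncertainties.
#'
#' @param spec an [SDDSpectrum-class]
#' @param lines character vector of element symbols (K-alpha assumed) or a
#'   list of [EmissionLine-class] objects; all line energies must lie inside
#'   the spectrum range
#' @param calib an [InstrumentCalibration-class] providing the detector
#'   response model
#' @param backgroundOrder polynomial background order per window (`0` =
#'   constant, default `1`)
#' @param windowFwhm half-width of the fit window in FWHM units
#' @return data.frame with one row per line: `element`, `transition`,
#'   `energy` (keV), `rate` (fitted count rate, 1/s, clipped at 0), `rateSE`
#'   (standard uncertainty, 1/s) and `converged`
#' @export
fitSpectrum <- function(spec, lines, calib, backgroundOrder = 1,
                        windowFwhm = 3.5) {
  stopifnot(is(spec, "SDDSpectrum"), is(calib, "InstrumentCalibration"),
            backgroundOrder >= 0)
  lines <- .resolveLines(lines)
  E <- energyAxis(spec)
  y <- spec@counts
  rng <- range(E)
  cen <- vapply(lines, function(l) l@energy, numeric(1))
  if (any(cen < rng[1] | cen > rng[2]))
    stop("all line energies must lie inside the spectrum's energy range")
  prof <- lapply(cen, responseProfile, calib = calib)
  sig <- vapply(prof, `[[`, numeric(1), "sigma")
  fw <- vapply(prof, `[[`, numeric(1), "fwhm")

  # merge overlapping fit windows; overlapping lines are fitted jointly
  lo <- cen - windowFwhm * fw
  hi <- cen + windowFwhm * fw
  ord <- order(cen)
  groups <- list()
  cur <- ord[1]
  curHi <- hi[ord[1]]
  for (i in ord[-1]) {
    if (lo[i] <= curHi) {
      cur <- c(cur, i)
      curHi <- max(curHi, hi[i])
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
      curHi <- hi[i]
    }
  }
  groups[[length(groups) + 1L]] <- cur

  n <- length(lines)
  rate <- rateSE <- rep(NA_real_, n)
  converged <- rep(FALSE, n)
  for (g in groups) {
    wlo <- min(lo[g]); whi <- max(hi[g])
    idx <- which(E >= wlo & E <= whi)
    npar <- length(g) + backgroundOrder + 1L
    if (length(idx) < npar)
      stop(sprintf(
        "degenerate fit window [%.3f, %.3f] keV: %d channels for %d parameters",
        wlo, whi, length(idx), npar))
    Ew <- E[idx]
    # unit-area Gaussian response x channel width: coefficient = total counts
    X <- vapply(g, function(i)
      stats::dnorm(Ew, cen[i], sig[i]) * spec@gain, numeric(length(idx)))
    X <- matrix(X, nrow = length(idx))
    mid <- mean(range(Ew)); hw <- diff(range(Ew)) / 2
    for (k in 0:backgroundOrder)
      X <- cbind(X, ((Ew - mid) / hw)^k)
    w <- 1 / pmax(y[idx], 1)
    fit <- tryCatch(stats::lm.wfit(X, y[idx], w), error = function(e) NULL)
    ok <- !is.null(fit) && fit$rank == ncol(X) &&
      all(is.finite(fit$coefficients[seq_along(g)]))
    if (ok) {
      xtwx <- crossprod(X * sqrt(w))
      covb <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
      ok <- !is.null(covb)
    }
    if (!ok) next
    area <- pmax(fit$coefficients[seq_along(g)], 0)
    se <- sqrt(pmax(diag(covb)[seq_along(g)], 0))
    rate[g] <- area / spec@liveTime
    rateSE[g] <- se / spec@liveTime
    converged[g] <- TRUE
  }
  data.frame(
    element = vapply(lines, function(l) l@element, character(1)),
    transition = vapply(lines, function(l) l@transition, character(1)),
    energy = cen, rate = rate, rateSE = rateSE, converged = converged,
    stringsAsFactors = FALSE
  )
}

#' Absolute (normalized) emission rate of a fitted line
#'
#' Normalizes a fitted count rate by the sine of the incidence angle, the
#' incident photon flux, the detection efficiency at the line energy and the
#' effective solid angle fraction:
#' \deqn{N_i / (\sin\theta_{in} \cdot \Phi_0 \cdot \epsilon(E_i) \cdot \Omega/4\pi)}
#'
#' @param rate fitted count rate, 1/s (vectorized)
#' @param lineEnergy line energy, keV (vectorized with `rate`)
#' @param calib an [InstrumentCalibration-class]
#' @return normalized emission rate (dimensionless group of the Sherman
#'   equation), proportional to `rate`
#' @export
absoluteIntensity <- function(rate, lineEnergy, calib) {
  eff <- efficiencyAt(calib, lineEnergy)
  if (any(eff <= 0))
    stop("detector efficiency is zero at a requested line energy")
  rate / (sin(calib@thetaIn * pi / 180) * calib@flux * eff *
            calib@solidAngle / (4 * pi))
}

#' Read / write spectra in the columnar text dialect
#'
#' Header lines `# live_time_s=`, `# e_offset_keV=`, `# e_gain_keV=`, then
#' one count per row. Integer counts round-trip bit-exactly.
#'
#' @param path file path
#' @return an [SDDSpectrum-class]
#' @export
readSpectrum <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^#", ln, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("malformed header: missing '%s='", key))
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m))
  }
  counts <- as.numeric(ln[!grepl("^#", ln) & nzchar(ln)])
  if (any(is.na(counts)) || any(counts < 0))
    stop("malformed spectrum body: counts must be non-negative numbers")
  sddSpectrum(counts, offset = getv("e_offset_keV"),
              gain = getv("e_gain_keV"), liveTime = getv("live_time_s"))
}

#' @rdname readSpectrum
#' @param spec an [SDDSpectrum-class]
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(is(spec, "SDDSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# live_time_s=%.15g", spec@liveTime),
    sprintf("# e_offset_keV=%.15g", spec@offset),
    sprintf("# e_gain_keV=%.15g", spec@gain),
    format(spec@counts, scientific = FALSE, trim = TRUE, digits = 15)
  ), con)
  invisible(path)
}
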