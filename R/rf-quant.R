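#' @include AllClasses.R AllGenerics.R
NULL

#' Self-absorption correction factor
#'
#' The finite-thickness absorption term of the Sherman equation,
#' \deqn{A = \frac{1 - \exp(-(\mu_0 + \mu_i)\,\rho\, d / \sin\theta)}
#'                {(\mu_0 + \mu_i)\,\rho\, d / \sin\theta},}
#' the depth-averaged attenuation of the incident beam during excitation and
#' of the fluorescence on its way back to the surface. Equals 1 in the
#' thin-film limit \eqn{\rho d \to 0} (handled analytically) and decreases
#' strictly with \eqn{\rho d} and \eqn{\mu_0 + \mu_i}.
#'
#' @param mu0 matrix mass attenuation at the incident energy, cm^2/g
#' @param mui matrix mass attenuation at the fluorescence energy, cm^2/g
#' @param rho matrix density, g/cm^3
#' @param d thickness, cm
#' @param theta effective beam angle w.r.t. the surface, degrees, in (0, 90]
#' @return dimensionless factor in (0, 1]; vectorized over all arguments
#' @export
absorptionCorrection <- function(mu0, mui, rho, d, theta = 45) {
  stopifnot(all(mu0 >= 0), all(mui >= 0), all(rho >= 0), all(d >= 0),
            all(theta > 0 & theta <= 90))
  x <- (mu0 + mui) * rho * d / sin(theta * pi / 180)
  ifelse(x < 1e-12, 1 - x / 2, -expm1(-x) / x)
}

#' Reference-free concentration from a fitted line intensity
#'
#' Inverts the Sherman equation: the normalized emission rate
#' ([absoluteIntensity()]) is divided by the fundamental-parameter product
#' \eqn{\gamma\, g\, \tau_K(E_0)}, the thickness and the absorption
#' correction, giving mass per unit volume. Counting and calibration
#' uncertainties are propagated in quadrature to a combined standard
#' uncertainty: the relative counting term from `rateSE` plus the relative
#' systematic budget of the calibration (fundamental parameters, efficiency,
#' solid angle, flux).
#'
#' @param rate fitted count rate N_i, 1/s
#' @param rateSE standard uncertainty of `rate`, 1/s
#' @param line an [EmissionLine-class] (or element symbol)
#' @param calib an [InstrumentCalibration-class]
#' @param matrix a [TissueMatrix-class]
#' @param d local sample thickness, cm (must be > 0)
#' @return named numeric vector: `concentration` and `csu`, both mg/cm^3
#' @export
concentration <- function(rate, rateSE, line, calib, matrix, d) {
  if (is.character(line)) line <- lineLookup(line)
  stopifnot(is(line, "EmissionLine"), is(calib, "InstrumentCalibration"),
            is(matrix, "TissueMatrix"))
  if (!(d > 0))
    stop("thickness d must be positive (volume concentration undefined at d = 0)")
  E0 <- calib@incidentEnergy
  if (E0 <= line@edge)
    stop(sprintf("incident energy %.3f keV is below the %s K edge (%.4f keV)",
                 E0, line@element, line@edge))
  tau <- tauK(line@element, E0)
  mu0 <- matrixMu(matrix, E0)
  mui <- matrixMu(matrix, line@energy)
  A <- absorptionCorrection(mu0, mui, matrix@density, d, calib@thetaIn)
  absInt <- absoluteIntensity(rate, line@energy, calib)
  C <- absInt / (line@fluorYield * line@transitionProb * tau * d * A)
  relSys2 <- sum(calib@relUncertainty^2)
  relStat <- if (rate > 0) rateSE / rate else 0
  csu <- if (rate > 0) C * sqrt(relStat^2 + relSys2) else {
    # zero signal: uncertainty from the counting noise floor alone
    absoluteIntensity(rateSE, line@energy, calib) /
      (line@fluorYield * line@transitionProb * tau * d * A)
  }
  c(concentration = C * 1000, csu = csu * 1000) # g/cm^3 -> mg/cm^3
}

#' Forward Sherman model: expected count rate for a known concentration
#'
#' The exact forward form of the quantification equation, used by the
#' synthetic-data generator and as the round-trip oracle for
#' [concentration()].
#'
#' @param C concentration, mg/cm^3
#' @inheritParams concentration
#' @return expected fluorescence count rate, 1/s
#' @export
expectedRate <- function(C, line, calib, matrix, d) {
  if (is.character(line)) line <- lineLookup(line)
  E0 <- calib@incidentEnergy
  tau <- tauK(line@element, E0)
  mu0 <- matrixMu(matrix, E0)
  mui <- matrixMu(matrix, line@energy)
  A <- absorptionCorrection(mu0, mui, matrix@density, d, calib@thetaIn)
  (C / 1000) * d * line@fluorYield * line@transitionProb * tau * A *
    sin(calib@thetaIn * pi / 180) * calib@flux *
    efficiencyAt(calib, line@energy) * calib@solidAngle / (4 * pi)
}

#' Sample thickness from substrate Si K-alpha attenuation
#'
#' Lambert-Beer inversion: the Si K-alpha fluorescence of the substrate is
#' attenuated by the overlying tissue on the way in (incident beam) and out
#' (fluorescence), so with \eqn{\theta_{in} = \theta_{out} = \theta}
#' \deqn{d = -\ln(I(d)/I_0)\,\sin\theta \,/\, ((\mu_s(E_0) + \mu_s(E_{Si}))\,\rho).}
#' \eqn{I_0} and \eqn{I(d)} are flux-normalized intensities
#' \eqn{\Phi_i/\Phi_0} with \eqn{\Phi_i = N_i/\epsilon(E)}; the efficiency
#' cancels between the tissue and substrate measurements of the same line.
#'
#' @param nTissue Si K-alpha count rate through the tissue, 1/s (>= 0)
#' @param fluxTissue incident flux during the tissue measurement, 1/s
#' @param nSubstrate Si K-alpha count rate of the bare substrate, 1/s (> 0)
#' @param fluxSubstrate incident flux during the substrate measurement, 1/s
#' @param matrix a [TissueMatrix-class] (tissue, not substrate)
#' @param calib an [InstrumentCalibration-class]
#' @return list with `d` (thickness, cm; `NA` when flagged) and `valid`
#'   (`FALSE` when the intensity ratio exceeds 1 -- negative thickness -- or
#'   the tissue intensity is 0, leaving d unbounded)
#' @export
thicknessFromSi <- function(nTissue, fluxTissue, nSubstrate, fluxSubstrate,
                            matrix, calib) {
  stopifnot(nTissue >= 0, nSubstrate > 0, fluxTissue > 0, fluxSubstrate > 0)
  si <- lineLookup("Si")
  ratio <- (nTissue / fluxTissue) / (nSubstrate / fluxSubstrate)
  if (ratio > 1 || ratio == 0)
    return(list(d = NA_real_, valid = FALSE))
  m <- matrixMu(matrix, calib@incidentEnergy) + matrixMu(matrix, si@energy)
  theta <- calib@thetaIn * pi / 180
  list(d = -log(ratio) * sin(theta) / (m * matrix@density), valid = TRUE)
}

#' Quantify a full map of spectra
#'
#' Per pixel: fit the element lines plus substrate Si K-alpha
#' ([fitSpectrum()]), recover the local thickness from the Si attenuation
#' ([thicknessFromSi()]), then invert the Sherman equation per element with
#' that thickness ([concentration()]). Pixels whose fit does not converge or
#' whose thickness is flagged are masked invalid and excluded from
#' summaries.
#'
#' @param spectra list of [SDDSpectrum-class], row-major (row = y, origin
#'   top-left), length `nx * ny`
#' @param substrate an [SDDSpectrum-class] of the bare substrate, measured
#'   with the same calibration
#' @param calib an [InstrumentCalibration-class]
#' @param matrix a [TissueMatrix-class]
#' @param elements element symbols to quantify (default P, S, Cl, K)
#' @param nx,ny map dimensions (`nx * ny == length(spectra)`)
#' @param pixelPitch pixel pitch, mm
#' @param backgroundOrder background polynomial order for [fitSpectrum()]
#' @param substrateFlux incident flux during the substrate reference
#'   measurement (defaults to the calibration flux)
#' @return a [ConcentrationMap-class]
#' @export
quantifyMap <- function(spectra, substrate, calib, matrix,
                        elements = c("P", "S", "Cl", "K"),
                        nx, ny, pixelPitch = 0.3, backgroundOrder = 1,
                        substrateFlux = calib@flux) {
  stopifnot(length(spectra) >= 1L, nx * ny == length(spectra))
  lines <- lapply(c(elements, "Si"), lineLookup)
  subFit <- fitSpectrum(substrate, list(lineLookup("Si")), calib,
                        backgroundOrder = backgroundOrder)
  if (!subFit$converged[1] || subFit$rate[1] <= 0)
    stop("substrate reference fit failed: no Si K-alpha rate")
  nSub <- subFit$rate[1]

  mk <- function() matrix(NA_real_, nrow = ny, ncol = nx)
  conc <- csu <- stats::setNames(replicate(length(elements), mk(),
                                           simplify = FALSE), elements)
  thick <- mk()
  valid <- matrix(FALSE, nrow = ny, ncol = nx)

  for (p in seq_along(spectra)) {
    iy <- (p - 1L) %/% nx + 1L
    ix <- (p - 1L) %% nx + 1L
    fit <- tryCatch(
      fitSpectrum(spectra[[p]], lines, calib,
                  backgroundOrder = backgroundOrder),
      error = function(e) NULL)
    if (is.null(fit) || !all(fit$converged)) next
    siRow <- which(fit$element == "Si")
    th <- thicknessFromSi(fit$rate[siRow], calib@flux, nSub, substrateFlux,
                          matrix, calib)
    if (!th$valid || th$d <= 0) next
    okPix <- TRUE
    vals <- list()
    for (i in seq_along(elements)) {
      r <- which(fit$element == elements[i])
      cc <- tryCatch(
        concentration(fit$rate[r], fit$rateSE[r], lines[[i]], calib,
                      matrix, th$d),
        error = function(e) NULL)
      if (is.null(cc)) { okPix <- FALSE; break }
      vals[[elements[i]]] <- cc
    }
    if (!okPix) next
    for (el in elements) {
      conc[[el]][iy, ix] <- vals[[el]][["concentration"]]
      csu[[el]][iy, ix] <- vals[[el]][["csu"]]
    }
    thick[iy, ix] <- th$d * 1e4 # cm -> micrometres
    valid[iy, ix] <- TRUE
  }
  if (!any(valid))
    stop("all pixels invalid: no quantifiable spectra in the map")
  new("ConcentrationMap", elements = elements, concentration = conc,
      csu = csu, thickness = thick, valid = valid, pixelPitch = pixelPitch)
}

#' @rdname elements
setMethod("elements", "ConcentrationMap", function(object) object@elements)

#' @rdname concentrations
setMethod("concentrations", "ConcentrationMap", function(object, element) {
  if (!element %in% object@elements) stop("element not in map: ", element)
  object@concentration[[element]]
})

#' @rdname concentrationCsu
setMethod("concentrationCsu", "ConcentrationMap", function(object, element) {
  if (!element %in% object@elements) stop("element not in map: ", element)
  object@csu[[element]]
})

#' @rdname thicknessField
setMethod("thicknessField", "ConcentrationMap", function(object) object@thickness)

#' @rdname validMask
setMethod("validMask", "ConcentrationMap", function(object) object@valid)

setMethod("show", "ConcentrationMap", function(object) {
  cat(sprintf("ConcentrationMap: %d x %d pixels (%.2f mm pitch), %d valid\n",
              ncol(object@valid), nrow(object@valid), object@pixelPitch,
              sum(object@valid)))
  cat("  elements:", paste(object@elements, collapse = ", "), "\n")
})

#' @describeIn mapSummary median +/- combined standard uncertainty of the
#'   median, mean +/- standard deviation and n per element, plus the
#'   thickness row. The uncertainty of the median combines the statistical
#'   term \eqn{1.2533 \cdot \mathrm{med}(csu_{pixel}) / \sqrt{n}} in
#'   quadrature with the systematic relative budget of `relUncertainty`
#'   (which does not shrink with n).
#' @param relUncertainty named relative systematic budget used for the
#'   median's combined standard uncertainty (defaults to the budget of
#'   [defaultCalibration()])
#' @export
setMethod("mapSummary", "ConcentrationMap",
          function(object, relUncertainty = c(fp = 0.20, efficiency = 0.05,
                                              solidAngle = 0.04, flux = 0.03)) {
  v <- object@valid
  n <- sum(v)
  if (n < 1L) stop("no valid pixels to summarize")
  relSys <- sqrt(sum(relUncertainty^2))
  rows <- lapply(object@elements, function(el) {
    x <- object@concentration[[el]][v]
    u <- object@csu[[el]][v]
    med <- stats::median(x)
    statTerm <- 1.2533 * stats::median(u) / sqrt(n)
    data.frame(quantity = paste0("C(", el, ")"), unit = "mg/cm^3",
               median = med,
               csu = sqrt(statTerm^2 + (relSys * med)^2),
               mean = mean(x), sd = stats::sd(x), n = n,
               stringsAsFactors = FALSE)
  })
  d <- object@thickness[v]
  medD <- stats::median(d)
  statD <- 1.2533 * stats::sd(d) / sqrt(n)
  rows[[length(rows) + 1L]] <-
    data.frame(quantity = "d", unit = "um", median = medD,
               csu = sqrt(statD^2 + (relSys * medD)^2),
               mean = mean(d), sd = stats::sd(d), n = n,
               stringsAsFactors = FALSE)
  do.call(rbind, rows)
})
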