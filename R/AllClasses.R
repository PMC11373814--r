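#' @import methods
NULL

#' EmissionLine: a characteristic fluorescence line with fundamental parameters
#'
#' Bundles the per-line atomic quantities consumed by the Sherman-equation
#' quantification: the line energy, the K-shell fluorescence yield
#' \eqn{\gamma}, and the transition probability \eqn{g} (the K\eqn{\alpha}
#' share of the K-series emission). The K-shell photoionization cross section
#' \eqn{\tau_K(E)} is energy dependent and is looked up via [tauK()].
#'
#' @slot element chemical symbol (e.g. `"S"`)
#' @slot transition transition label (`"Ka"`)
#' @slot energy line energy in keV
#' @slot fluorYield fluorescence yield, dimensionless in (0, 1)
#' @slot transitionProb transition probability, dimensionless in (0, 1]
#' @slot edge K absorption edge energy in keV
#' @export
setClass("EmissionLine",
  representation(
    element = "character",
    transition = "character",
    energy = "numeric",
    fluorYield = "numeric",
    transitionProb = "numeric",
    edge = "numeric"
  )
)

setValidity("EmissionLine", function(object) {
  msg <- character()
  if (length(object@element) != 1L || !nzchar(object@element))
    msg <- c(msg, "element must be a single chemical symbol")
  if (!(length(object@energy) == 1L && object@energy > 0))
    msg <- c(msg, "line energy must be a single positive value (keV)")
  if (!(object@fluorYield > 0 && object@fluorYield < 1))
    msg <- c(msg, "fluorescence yield must lie in (0, 1)")
  if (!(object@transitionProb > 0 && object@transitionProb <= 1))
    msg <- c(msg, "transition probability must lie in (0, 1]")
  if (!(object@edge > object@energy))
    msg <- c(msg, "absorption edge must lie above the line energy")
  if (length(msg)) msg else TRUE
})

#' TissueMatrix: elemental composition and density of the specimen matrix
#'
#' The matrix enters quantification only through its mass attenuation
#' coefficient \eqn{\mu_s(E)}, computed by the mixture rule from the bundled
#' per-element tables (see [matrixMu()]).
#'
#' @slot massFractions named numeric vector of mass fractions, summing to 1
#' @slot density matrix density \eqn{\rho} in g/cm^3
#' @slot thickness optional nominal thickness in cm (`NA_real_` if unknown)
#' @export
setClass("TissueMatrix",
  representation(
    massFractions = "numeric",
    density = "numeric",
    thickness = "numeric"
  ),
  prototype(thickness = NA_real_)
)

setValidity("TissueMatrix", function(object) {
  msg <- character()
  w <- object@massFractions
  if (is.null(names(w)) || any(!nzchar(names(w))))
    msg <- c(msg, "mass fractions must be named by chemical symbol")
  if (any(w < 0))
    msg <- c(msg, "mass fractions must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "mass fractions must sum to 1 (within 1e-9)")
  if (!(length(object@density) == 1L && object@density > 0))
    msg <- c(msg, "density must be a single positive value (g/cm^3)")
  if (!is.na(object@thickness) && object@thickness < 0)
    msg <- c(msg, "thickness must be >= 0 when given")
  if (length(msg)) msg else TRUE
})

#' InstrumentCalibration: radiometric and geometric calibration of the setup
#'
#' Holds everything the reference-free quantification needs to convert a
#' fitted count rate into an absolute emitted intensity: incident photon
#' energy and flux, detector efficiency curve, effective solid angle,
#' beam/detector geometry, and the detector energy-resolution model
#' (electronic noise plus Fano broadening). The relative systematic
#' uncertainty budget used for combined standard uncertainties is carried
#' here as well.
#'
#' @slot incidentEnergy incident photon energy E0 in keV
#' @slot flux incident photon flux \eqn{\Phi_0} in photons/s
#' @slot efficiency two-column matrix (energy keV, efficiency in (0, 1])
#' @slot solidAngle effective solid angle of detection \eqn{\Omega} in sr
#' @slot thetaIn beam incidence angle w.r.t. sample surface, degrees
#' @slot thetaOut detection angle w.r.t. sample surface, degrees
#' @slot noiseFWHM electronic noise contribution to FWHM, eV
#' @slot fano Fano factor of silicon (dimensionless)
#' @slot wEH electron-hole pair creation energy of silicon, eV
#' @slot relUncertainty named relative systematic uncertainties
#'   (`fp`, `efficiency`, `solidAngle`, `flux`)
#' @export
setClass("InstrumentCalibration",
  representation(
    incidentEnergy = "numeric",
    flux = "numeric",
    efficiency = "matrix",
    solidAngle = "numeric",
    thetaIn = "numeric",
    thetaOut = "numeric",
    noiseFWHM = "numeric",
    fano = "numeric",
    wEH = "numeric",
    relUncertainty = "numeric"
  )
)

setValidity("InstrumentCalibration", function(object) {
  msg <- character()
  if (!(object@incidentEnergy > 0))
    msg <- c(msg, "incident energy must be positive")
  if (!(object@flux > 0))
    msg <- c(msg, "incident photon flux must be positive")
  eff <- object@efficiency
  if (ncol(eff) != 2L || any(eff[, 2] <= 0) || any(eff[, 2] > 1))
    msg <- c(msg, "efficiency must be a two-column (energy, value) grid with values in (0, 1]")
  if (is.unsorted(eff[, 1], strictly = TRUE))
    msg <- c(msg, "efficiency energy grid must be strictly increasing")
  if (!(object@solidAngle > 0 && object@solidAngle <= 4 * pi))
    msg <- c(msg, "solid angle must lie in (0, 4*pi]")
  if (!(object@thetaIn > 0 && object@thetaIn <= 90))
    msg <- c(msg, "incidence angle must lie in (0, 90] degrees")
  if (!(object@thetaOut > 0 && object@thetaOut <= 90))
    msg <- c(msg, "detection angle must lie in (0, 90] degrees")
  if (object@noiseFWHM < 0 || object@fano < 0 || object@wEH <= 0)
    msg <- c(msg, "noise FWHM and fano must be >= 0, pair-creation energy > 0")
  if (length(msg)) msg else TRUE
})

#' SDDSpectrum: an energy-dispersive fluorescence spectrum
#'
#' Raw measurand of the XRF stage: counts per channel on an affine energy
#' calibration (offset + gain * channel, channels 0-based) with the live time
#' of the acquisition.
#'
#' @slot counts non-negative counts per channel
#' @slot offset energy of channel 0, keV
#' @slot gain channel width, keV
#' @slot liveTime live time of the acquisition, s
#' @export
setClass("SDDSpectrum",
  representation(
    counts = "numeric",
    offset = "numeric",
    gain = "numeric",
    liveTime = "numeric"
  )
)

setValidity("SDDSpectrum", function(object) {
  msg <- character()
  if (length(object@counts) < 2L)
    msg <- c(msg, "spectrum must have at least two channels")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be finite and non-negative")
  if (!(object@gain > 0))
    msg <- c(msg, "energy gain must be positive (strictly increasing axis)")
  if (!(object@liveTime > 0))
    msg <- c(msg, "live time must be positive")
  if (length(msg)) msg else TRUE
})

#' ConcentrationMap: lateral elemental concentration fields with uncertainties
#'
#' Result of per-pixel reference-free quantification: one concentration field
#' (mg/cm^3) with a combined-standard-uncertainty field per element, the
#' recovered thickness field (micrometres), and a per-pixel validity mask
#' shared by all elements. Maps are indexed `[row = y, col = x]`, origin
#' top-left.
#'
#' @slot elements character vector of quantified element symbols
#' @slot concentration named list of numeric matrices, mg/cm^3
#' @slot csu named list of numeric matrices, combined standard uncertainty,
#'   mg/cm^3
#' @slot thickness numeric matrix, micrometres
#' @slot valid logical matrix, `TRUE` where the pixel quantified successfully
#' @slot pixelPitch pixel pitch in mm (beam footprint / mapping step size)
#' @export
setClass("ConcentrationMap",
  representation(
    elements = "character",
    concentration = "list",
    csu = "list",
    thickness = "matrix",
    valid = "matrix",
    pixelPitch = "numeric"
  )
)

setValidity("ConcentrationMap", function(object) {
  msg <- character()
  dm <- dim(object@valid)
  if (!is.logical(object@valid))
    msg <- c(msg, "validity mask must be logical")
  if (!identical(dim(object@thickness), dm))
    msg <- c(msg, "thickness field must match the mask dimensions")
  if (!setequal(names(object@concentration), object@elements) ||
      !setequal(names(object@csu), object@elements))
    msg <- c(msg, "concentration and csu lists must be keyed by the element set")
  for (el in object@elements) {
    C <- object@concentration[[el]]
    if (!identical(dim(C), dm)) {
      msg <- c(msg, sprintf("field for %s must match the mask dimensions", el))
      next
    }
    if (any(C[object@valid] < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("valid concentrations for %s must be >= 0", el))
  }
  if (any(object@thickness[object@valid] < 0, na.rm = TRUE))
    msg <- c(msg, "valid thicknesses must be >= 0")
  if (!(length(object@pixelPitch) == 1L && object@pixelPitch > 0))
    msg <- c(msg, "pixel pitch must be a single positive value (mm)")
  if (length(msg)) msg else TRUE
})

#' FTIRSpectrum: a mid-infrared absorbance spectrum
#'
#' Wavenumber axis in 1/cm (stored strictly increasing; descending input is
#' normalised by the constructor) with absorbance in AU.
#'
#' @slot wavenumber strictly increasing wavenumber axis, 1/cm
#' @slot absorbance absorbance values, AU
#' @export
setClass("FTIRSpectrum",
  representation(
    wavenumber = "numeric",
    absorbance = "numeric"
  )
)

setValidity("FTIRSpectrum", function(object) {
  msg <- character()
  w <- object@wavenumber
  if (length(w) != length(object@absorbance))
    msg <- c(msg, "axis and absorbance must have equal length")
  if (is.unsorted(w, strictly = TRUE))
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  if (any(!is.finite(object@absorbance)))
    msg <- c(msg, "absorbance must be finite")
  # point spacing must resolve the amide window when the spectrum covers it
  inw <- w >= 1480 & w <= 1720
  if (sum(inw) > 1L && max(diff(w[inw])) > 8)
    msg <- c(msg, "point spacing within 1480-1720 1/cm must be <= 8 1/cm")
  if (length(msg)) msg else TRUE
})

#' AmideModel: fitted pseudo-Voigt decomposition of the amide I band
#'
#' @slot components data.frame with columns `assignment` (one of `beta_s`,
#'   `alpha`, `random`, `beta_t`), `center` (1/cm), `fwhm` (1/cm), `eta`
#'   (Lorentzian mixing, in `[0, 1]`), `area` (AU/cm)
#' @slot amideIIArea integrated amide II band area, AU/cm (`NA` if the
#'   spectrum did not cover the amide II window)
#' @slot residualNorm root-mean-square fit residual, AU
#' @slot converged logical, optimizer convergence flag
#' @export
setClass("AmideModel",
  representation(
    components = "data.frame",
    amideIIArea = "numeric",
    residualNorm = "numeric",
    converged = "logical"
  )
)

setValidity("AmideModel", function(object) {
  msg <- character()
  cmp <- object@components
  need <- c("assignment", "center", "fwhm", "eta", "area")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, "components must have assignment/center/fwhm/eta/area columns")
  else {
    if (!all(cmp$assignment %in% c("beta_s", "alpha", "random", "beta_t",
                                   "amide_II")))
      msg <- c(msg, "unknown secondary-structure assignment")
    if (any(cmp$area < 0))
      msg <- c(msg, "component areas must be >= 0")
    if (any(cmp$eta < 0 | cmp$eta > 1))
      msg <- c(msg, "mixing parameter eta must lie in [0, 1]")
  }
  if (!is.na(object@amideIIArea) && object@amideIIArea <= 0)
    msg <- c(msg, "amide II area must be positive when present")
  if (length(msg)) msg else TRUE
})

#' ConditionProfile: generator parameters for one tissue condition
#'
#' Defines the statistical ground truth the synthetic-data generator emulates
#' for one experimental condition: per-element median concentrations, median
#' section thickness, the number of map pixels, the lognormal heterogeneity,
#' the spatial correlation length, and the Cl-vs-P/K anti-correlation seen in
#' treated tissue. FTIR secondary-structure area ratios (relative to amide
#' II) are carried alongside.
#'
#' @slot label condition label (`HP`, `PC`, `2Gy-D3`, `2Gy-D12`, `6Gy-D3`,
#'   `6Gy-D12`)
#' @slot medians named per-element median concentrations, mg/cm^3
#' @slot thicknessMedian median section thickness, micrometres
#' @slot n number of valid map pixels for the condition
#' @slot sigma lognormal shape parameter of the concentration fields
#' @slot corLength spatial correlation length, pixels
#' @slot antiCorrelation whether Cl is anti-correlated with P and K
#' @slot antiStrength loading of the shared latent factor, in [0, 1)
#' @slot ftirRatios named secondary-structure area ratios vs amide II
#'   (`beta_s`, `alpha`, `random`, `beta_t`)
#' @export
setClass("ConditionProfile",
  representation(
    label = "character",
    medians = "numeric",
    thicknessMedian = "numeric",
    n = "integer",
    sigma = "numeric",
    corLength = "numeric",
    antiCorrelation = "logical",
    antiStrength = "numeric",
    ftirRatios = "numeric"
  )
)

setValidity("ConditionProfile", function(object) {
  msg <- character()
  if (any(object@medians <= 0) || is.null(names(object@medians)))
    msg <- c(msg, "element medians must be positive and named")
  if (!(object@thicknessMedian > 0))
    msg <- c(msg, "thickness median must be positive")
  if (!(object@n >= 1L))
    msg <- c(msg, "pixel count n must be >= 1")
  if (object@sigma < 0)
    msg <- c(msg, "lognormal sigma must be >= 0")
  if (!(object@antiStrength >= 0 && object@antiStrength < 1))
    msg <- c(msg, "anti-correlation strength must lie in [0, 1)")
  if (length(object@ftirRatios) &&
      (any(object@ftirRatios < 0) ||
       !all(c("beta_s", "alpha", "random", "beta_t") %in% names(object@ftirRatios))))
    msg <- c(msg, "ftirRatios must name beta_s/alpha/random/beta_t, all >= 0")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: simulated concentration and thickness fields
#'
#' @slot fields named list of per-element concentration matrices, mg/cm^3
#' @slot thickness thickness field, micrometres
#' @slot profile the [ConditionProfile-class] that produced the fields
#' @slot seed integer seed the fields are reproducible from
#' @export
setClass("GroundTruth",
  representation(
    fields = "list",
    thickness = "matrix",
    profile = "ConditionProfile",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  dm <- dim(object@thickness)
  for (el in names(object@fields)) {
    f <- object@fields[[el]]
    if (!identical(dim(f), dm))
      msg <- c(msg, sprintf("field %s must match the thickness dimensions", el))
    else if (any(f <= 0))
      msg <- c(msg, sprintf("field %s must be strictly positive", el))
  }
  if (any(object@thickness <= 0))
    msg <- c(msg, "thickness field must be strictly positive")
  if (length(msg)) msg else TRUE
})
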