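#' @include AllClasses.R
NULL

#' Energy axis of a spectrum
#' @param object an [SDDSpectrum-class]
#' @return numeric vector of channel energies, keV
#' @export
setGeneric("energyAxis", function(object) standardGeneric("energyAxis"))

#' Counts per channel
#' @param object an [SDDSpectrum-class]
#' @return numeric vector of counts
#' @export
setGeneric("spectrumCounts", function(object) standardGeneric("spectrumCounts"))

#' Live time of an acquisition
#' @param object an [SDDSpectrum-class]
#' @return live time, s
#' @export
setGeneric("liveTime", function(object) standardGeneric("liveTime"))

#' Quantified element symbols
#' @param object a [ConcentrationMap-class] or [GroundTruth-class]
#' @return character vector of element symbols
#' @export
setGeneric("elements", function(object) standardGeneric("elements"))

#' Concentration field of one element
#' @param object a [ConcentrationMap-class] or [GroundTruth-class]
#' @param element element symbol
#' @return numeric matrix, mg/cm^3
#' @export
setGeneric("concentrations",
           function(object, element) standardGeneric("concentrations"))

#' Combined-standard-uncertainty field of one element
#' @param object a [ConcentrationMap-class]
#' @param element element symbol
#' @return numeric matrix, mg/cm^3
#' @export
setGeneric("concentrationCsu",
           function(object, element) standardGeneric("concentrationCsu"))

#' Thickness field
#' @param object a [ConcentrationMap-class] or [GroundTruth-class]
#' @return numeric matrix, micrometres
#' @export
setGeneric("thicknessField", function(object) standardGeneric("thicknessField"))

#' Per-pixel validity mask
#' @param object a [ConcentrationMap-class]
#' @return logical matrix
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' Map summary in the reporting layout
#'
#' Per element (and for the thickness field): median with the combined
#' standard uncertainty of the median, mean with standard deviation, and the
#' number of valid pixels.
#'
#' @param object a [ConcentrationMap-class]
#' @param ... further arguments for methods
#' @return a data.frame, one row per element plus one for thickness
#' @export
setGeneric("mapSummary", function(object, ...) standardGeneric("mapSummary"))

#' Wavenumber axis of an FTIR spectrum
#' @param object an [FTIRSpectrum-class]
#' @return numeric vector, 1/cm
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' Absorbance values of an FTIR spectrum
#' @param object an [FTIRSpectrum-class]
#' @return numeric vector, AU
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' Secondary-structure area ratios relative to amide II
#'
#' Sums fitted component areas within each secondary-structure group and
#' divides by the integrated amide II band area. The total amide I / amide II
#' ratio is the sum of the four group ratios by construction.
#'
#' @param object an [AmideModel-class]
#' @return named numeric vector with elements `beta_s`, `alpha`, `random`,
#'   `beta_t`, `amide_I_total`
#' @export
setGeneric("structureRatios", function(object) standardGeneric("structureRatios"))
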