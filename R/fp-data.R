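#' @include AllClasses.R AllGenerics.R
NULL

# Package-level cache for the bundled fundamental-parameter tables.
.fpEnv <- new.env(parent = emptyenv())

.fpRead <- function(name) {
  key <- paste0("tab_", name)
  if (!is.null(.fpEnv[[key]])) return(.fpEnv[[key]])
  path <- getOption(paste0("xrftir.fp.", name),
                    system.file("extdata", paste0(name, ".tsv"),
                                package = "xrftir", mustWork = TRUE))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  .fpEnv[[key]] <- tab
  tab
}

#' Bundled fundamental-parameter provider
#'
#' The fundamental parameters (mass attenuation, K-shell photoionization
#' cross sections, line energies, fluorescence yields, transition
#' probabilities) are shipped as delimited text under `inst/extdata` with
#' their source compilations named in the file headers. An external provider
#' can be plugged in by pointing the options `xrftir.fp.attenuation`,
#' `xrftir.fp.tau_k` and `xrftir.fp.emission_lines` at files with the same
#' columns.
#'
#' @return invisibly, a list of the three tables
#' @export
fpTables <- function() {
  invisible(list(
    attenuation = .fpRead("attenuation"),
    tau_k = .fpRead("tau_k"),
    emission_lines = .fpRead("emission_lines")
  ))
}

# log-log linear interpolation on a strictly increasing grid; errors outside.
.logLogInterp <- function(x, y, xout, what = "value") {
  if (any(xout < x[1] - 1e-12) || any(xout > x[length(x)] + 1e-12))
    stop(sprintf("requested energy outside the tabulated %s grid [%g, %g] keV",
                 what, x[1], x[length(x)]))
  exp(stats::approx(log(x), log(y), xout = log(xout), rule = 2)$y)
}

#' Mass attenuation coefficient of a single element
#'
#' Log-log linear interpolation of the bundled attenuation table. Absorption
#' edges are represented by closely straddling grid points, so interpolation
#' stays on one side of each edge.
#'
#' @param element chemical symbol
#' @param energy photon energy (keV), vectorized
#' @return mass attenuation coefficient, cm^2/g
#' @export
elementMu <- function(element, energy) {
  tab <- .fpRead("attenuation")
  sel <- tab$element == element
  if (!any(sel))
    stop(sprintf("element '%s' missing from the bundled attenuation tables", element))
  sub <- tab[sel, ]
  .logLogInterp(sub$energy_keV, sub$mu_cm2_g, energy,
                what = sprintf("attenuation (%s)", element))
}

#' Matrix mass attenuation coefficient by the mixture rule
#'
#' \eqn{\mu_s(E) = \sum_j w_j \mu_j(E)} over the matrix elements, the value
#' entering the Sherman-equation absorption correction.
#'
#' @param matrix a [TissueMatrix-class]
#' @param energy photon energy (keV), vectorized
#' @return mass attenuation coefficient of the mixture, cm^2/g
#' @export
matrixMu <- function(matrix, energy) {
  stopifnot(is(matrix, "TissueMatrix"))
  w <- matrix@massFractions
  mu <- 0
  for (el in names(w)) {
    if (w[[el]] == 0) next
    mu <- mu + w[[el]] * elementMu(el, energy)
  }
  mu
}

#' K-shell photoionization cross section
#'
#' \eqn{\tau_K(E)} of the bundled tables, defined for excitation energies
#' above the element's K absorption edge.
#'
#' @param element chemical symbol
#' @param energy excitation energy (keV), vectorized
#' @return K-shell photoionization cross section, cm^2/g
#' @export
tauK <- function(element, energy) {
  tab <- .fpRead("tau_k")
  sel <- tab$element == element
  if (!any(sel))
    stop(sprintf("element '%s' missing from the bundled photoionization tables", element))
  sub <- tab[sel, ]
  if (any(energy < sub$energy_keV[1]))
    stop(sprintf("excitation energy below the %s K absorption edge (%.4f keV)",
                 element, sub$energy_keV[1]))
  .logLogInterp(sub$energy_keV, sub$tau_cm2_g, energy,
                what = sprintf("tau_K (%s)", element))
}

#' Look up a fully populated emission line
#'
#' @param element chemical symbol (P, S, Cl, K, Si are bundled)
#' @param transition transition label; `"Ka"` (synonyms `"K-L3"`,
#'   `"Kalpha"`) is bundled
#' @return an [EmissionLine-class]
#' @examples
#' lineLookup("S", "Ka")
#' @export
lineLookup <- function(element, transition = "Ka") {
  transition <- switch(transition,
                       "K-L3" = "Ka", "Kalpha" = "Ka", "Ka" = "Ka",
                       transition)
  tab <- .fpRead("emission_lines")
  row <- tab[tab$element == element & tab$transition == transition, ]
  if (nrow(row) == 0L) {
    if (!element %in% tab$element)
      stop(sprintf("unknown element '%s'", element))
    stop(sprintf("unsupported transition '%s' for element '%s'",
                 transition, element))
  }
  new("EmissionLine",
      element = row$element, transition = row$transition,
      energy = row$energy_keV, fluorYield = row$fluor_yield,
      transitionProb = row$transition_prob, edge = row$edge_keV)
}

#' Construct a tissue matrix
#'
#' @param massFractions named numeric vector of mass fractions (must sum
#'   to 1 within 1e-9)
#' @param density matrix density, g/cm^3
#' @param thickness optional nominal thickness, cm
#' @return a [TissueMatrix-class]
#' @export
tissueMatrix <- function(massFractions, density, thickness = NA_real_) {
  new("TissueMatrix", massFractions = massFractions, density = density,
      thickness = thickness)
}

#' Default dried-tissue matrix
#'
#' Representative composition of lyophilised soft tissue: H 6%, C 50%,
#' N 12%, O 30%, with the remaining 2% distributed evenly over the four
#' quantified elements (P, S, Cl, K); density 1.35 g/cm^3. Intended as an
#' overridable default -- the matrix composition of a real section is rarely
#' known and enters only through \eqn{\mu_s(E)}.
#'
#' @param density matrix density, g/cm^3
#' @return a [TissueMatrix-class]
#' @export
defaultTissueMatrix <- function(density = 1.35) {
  tissueMatrix(
    c(H = 0.06, C = 0.50, N = 0.12, O = 0.30,
      P = 0.005, S = 0.005, Cl = 0.005, K = 0.005),
    density = density
  )
}

setMethod("show", "EmissionLine", function(object) {
  cat(sprintf("%s %s line: %.4f keV (edge %.4f keV), yield %.3f, g %.3f\n",
              object@element, object@transition, object@energy,
              object@edge, object@fluorYield, object@transitionProb))
})

setMethod("show", "TissueMatrix", function(object) {
  cat("TissueMatrix, density", object@density, "g/cm^3\n")
  w <- object@massFractions
  cat(paste(sprintf("  %-2s %6.3f", names(w), w), collapse = "\n"), "\n")
})
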