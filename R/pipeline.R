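#' @include AllClasses.R AllGenerics.R
NULL

.fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

#' Write / read a concentration map as delimited text
#'
#' One grid file per element (`<prefix>_C_<el>.tsv`) plus uncertainty grids,
#' the thickness and validity grids, a tidy long-format table
#' (`<prefix>_long.csv`: x, y, element, C, csu, d, valid; 0-based indices,
#' origin top-left) and a small metadata header. Values are written with 12
#' significant digits; the mask round-trips exactly.
#'
#' @param map a [ConcentrationMap-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
writeConcentrationMap <- function(map, dir, prefix = "map") {
  stopifnot(is(map, "ConcentrationMap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wgrid <- function(m, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(matrix(.fmt(m), nrow = nrow(m)), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }
  for (el in map@elements) {
    paths <- c(paths, wgrid(map@concentration[[el]], paste0("C_", el)),
               wgrid(map@csu[[el]], paste0("csu_", el)))
  }
  paths <- c(paths, wgrid(map@thickness, "thickness"))
  pv <- file.path(dir, paste0(prefix, "_valid.tsv"))
  utils::write.table(matrix(as.integer(map@valid), nrow = nrow(map@valid)),
                     pv, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths <- c(paths, pv)
  long <- do.call(rbind, lapply(map@elements, function(el) {
    idx <- which(!is.na(map@concentration[[el]]) | TRUE, arr.ind = TRUE)
    data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L, element = el,
               C = map@concentration[[el]][idx],
               csu = map@csu[[el]][idx],
               d = map@thickness[idx],
               valid = map@valid[idx], stringsAsFactors = FALSE)
  }))
  pl <- file.path(dir, paste0(prefix, "_long.csv"))
  utils::write.csv(long, pl, row.names = FALSE)
  pm <- file.path(dir, paste0(prefix, "_meta.yml"))
  yaml::write_yaml(list(elements = as.list(map@elements),
                        pixel_pitch_mm = map@pixelPitch,
                        ny = nrow(map@valid), nx = ncol(map@valid)), pm)
  invisible(c(paths, pl, pm))
}

#' @rdname writeConcentrationMap
#' @export
readConcentrationMap <- function(dir, prefix = "map") {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yml")))
  rgrid <- function(name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    as.matrix(utils::read.table(p, sep = "\t", na.strings = "NA",
                                colClasses = "numeric"))
  }
  els <- unlist(meta$elements)
  conc <- csu <- stats::setNames(vector("list", length(els)), els)
  for (el in els) {
    conc[[el]] <- unname(rgrid(paste0("C_", el)))
    csu[[el]] <- unname(rgrid(paste0("csu_", el)))
  }
  valid <- unname(rgrid("valid")) > 0
  new("ConcentrationMap", elements = els, concentration = conc, csu = csu,
      thickness = unname(rgrid("thickness")), valid = valid,
      pixelPitch = meta$pixel_pitch_mm)
}

#' Validate a pipeline configuration
#'
#' Checks the run configuration and returns *all* problems found (not just
#' the first) as a character vector; an empty vector means the configuration
#' is valid.
#'
#' @param config a named list (or the result of [yaml::read_yaml()])
#' @return character vector of validation messages
#' @export
validateConfig <- function(config) {
  msg <- character()
  need <- function(cond, text) if (!isTRUE(cond)) msg <<- c(msg, text)
  need(is.list(config), "config must be a named list")
  if (!is.list(config)) return(msg)
  need(!is.null(config$output_dir), "missing field: output_dir")
  need(is.numeric(config$seed) && length(config$seed) == 1,
       "missing or non-scalar field: seed")
  conds <- config$conditions
  need(length(conds) >= 1 && all(unlist(conds) %in% listConditions()),
       paste0("conditions must be a non-empty subset of: ",
              paste(listConditions(), collapse = ", ")))
  cal <- config$calibration
  if (is.null(cal)) msg <- c(msg, "missing section: calibration")
  else {
    need(is.numeric(cal$incident_energy_keV) && cal$incident_energy_keV > 0,
         "calibration: missing or invalid incident_energy_keV")
    need(is.numeric(cal$flux_s1) && cal$flux_s1 > 0,
         "calibration: missing or invalid flux_s1")
  }
  grid <- config$grid
  need(is.numeric(grid$nx) && is.numeric(grid$ny) && grid$nx >= 1 && grid$ny >= 1,
       "grid: nx and ny must be >= 1")
  els <- unlist(config$elements)
  if (length(els))
    for (el in els)
      if (inherits(try(lineLookup(el), silent = TRUE), "try-error"))
        msg <- c(msg, paste0("elements: no bundled emission line for '", el, "'"))
  msg
}

.calibFromConfig <- function(cal) {
  instrumentCalibration(
    incidentEnergy = cal$incident_energy_keV,
    flux = cal$flux_s1,
    efficiency = if (is.null(cal$efficiency)) 0.8 else cal$efficiency,
    solidAngle = if (is.null(cal$solid_angle_sr)) 0.1 else cal$solid_angle_sr,
    thetaIn = if (is.null(cal$theta_in_deg)) 45 else cal$theta_in_deg,
    thetaOut = if (is.null(cal$theta_out_deg)) 45 else cal$theta_out_deg,
    noiseFWHM = if (is.null(cal$noise_fwhm_eV)) 60 else cal$noise_fwhm_eV,
    fano = if (is.null(cal$fano)) 0.114 else cal$fano
  )
}

.matrixFromConfig <- function(mat) {
  if (is.null(mat)) return(defaultTissueMatrix())
  if (is.null(mat$mass_fractions))
    return(defaultTissueMatrix(
      density = if (is.null(mat$density_g_cm3)) 1.35 else mat$density_g_cm3))
  tissueMatrix(unlist(mat$mass_fractions),
               density = if (is.null(mat$density_g_cm3)) 1.35 else mat$density_g_cm3)
}

#' Run the full hybrid pipeline from a configuration
#'
#' Simulates (or, in future, loads) per-condition XRF maps and FTIR
#' ensembles, quantifies every map (spectrum deconvolution, per-pixel
#' thickness recovery, Sherman-equation inversion), summarises the
#' concentration maps, fits the FTIR ensembles and aggregates
#' secondary-structure ratios, compares all conditions against the
#' reference with the Mann-Whitney-Wilcoxon test, and writes the four
#' report tables plus a provenance manifest. Identical configurations
#' produce byte-identical numeric tables.
#'
#' @param config configuration list or path to a YAML file
#' @return invisibly, a list with the four tables (`summaries`, `ratios`,
#'   `comparisons`, and per-condition `maps`) and the output `paths`
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))

  outDir <- config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  calib <- .calibFromConfig(config$calibration)
  matrix <- .matrixFromConfig(config$matrix)
  els <- if (length(config$elements)) unlist(config$elements) else c("P", "S", "Cl", "K")
  conds <- unlist(config$conditions)
  nx <- config$grid$nx; ny <- config$grid$ny
  dwell <- if (is.null(config$dwell)) 5 else config$dwell
  bgOrder <- if (is.null(config$fit$background_order)) 1 else config$fit$background_order
  nFtir <- if (is.null(config$ftir$n)) 100 else config$ftir$n
  ftirNoise <- if (is.null(config$ftir$noise)) 0.01 else config$ftir$noise
  reference <- if (is.null(config$stats$reference)) "PC" else config$stats$reference

  maps <- list()
  summaries <- list()
  ratioRows <- list()
  for (i in seq_along(conds)) {
    cond <- conds[i]
    prof <- conditionProfile(cond)
    truth <- simulateMap(prof, nx = nx, ny = ny, seed = seed + i)
    fwd <- forwardXrf(truth, calib, matrix, dwell = dwell, seed = seed + 100L + i)
    map <- quantifyMap(fwd$spectra, fwd$substrate, calib, matrix,
                       elements = els, nx = fwd$nx, ny = fwd$ny,
                       backgroundOrder = bgOrder)
    maps[[cond]] <- map
    writeConcentrationMap(map, outDir, prefix = paste0("map_", gsub("[^A-Za-z0-9]", "_", cond)))
    s <- mapSummary(map)
    summaries[[cond]] <- cbind(condition = cond, s, stringsAsFactors = FALSE)

    ens <- simulateFtir(cond, n = nFtir, seed = seed + 200L + i, noise = ftirNoise)
    st <- fitAmideEnsemble(ens)$stats
    ratioRows[[cond]] <- cbind(condition = cond, st, stringsAsFactors = FALSE)
  }
  summaryTab <- do.call(rbind, summaries)
  ratioTab <- do.call(rbind, ratioRows)
  comparisons <- if (length(conds) >= 2 && reference %in% conds)
    compareConditions(maps, reference = reference, elements = els)
  else NULL

  pSummary <- file.path(outDir, "map_summaries.csv")
  pRatios <- file.path(outDir, "ftir_ratios.csv")
  pComp <- file.path(outDir, "group_comparisons.csv")
  utils::write.csv(summaryTab, pSummary, row.names = FALSE)
  utils::write.csv(ratioTab, pRatios, row.names = FALSE)
  if (!is.null(comparisons)) utils::write.csv(comparisons, pComp, row.names = FALSE)

  # provenance manifest: configuration echo, seeds, versions, output hashes
  pConfig <- file.path(outDir, "config_echo.yml")
  yaml::write_yaml(config, pConfig)
  outputs <- c(pSummary, pRatios, if (!is.null(comparisons)) pComp)
  manifest <- list(
    package = "xrftir",
    version = as.character(utils::packageVersion("xrftir")),
    seed = seed,
    config_md5 = unname(tools::md5sum(pConfig)),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  pManifest <- file.path(outDir, "manifest.yml")
  yaml::write_yaml(manifest, pManifest)

  invisible(list(summaries = summaryTab, ratios = ratioTab,
                 comparisons = comparisons, maps = maps,
                 paths = c(summary = pSummary, ratios = pRatios,
                           comparisons = if (!is.null(comparisons)) pComp,
                           manifest = pManifest)))
}

#' Write a self-contained simulated fixture directory
#'
#' Simulates one condition's map, forward-models its spectra, and writes
#' everything a downstream quantification needs: one spectrum text file per
#' pixel (`spectra/pixel_<y>_<x>.txt`), the substrate reference, the
#' calibration record, the ground-truth concentration and thickness tables,
#' and a manifest with all parameters and seeds.
#'
#' @param label condition label, see [listConditions()]
#' @param nx,ny grid dimensions
#' @param seed integer seed (map and noise seeds are derived from it)
#' @param dir output directory
#' @param calib an [InstrumentCalibration-class]
#' @param matrix a [TissueMatrix-class]
#' @param dwell per-pixel dwell time, s
#' @return invisibly, the fixture directory
#' @export
writeSimulatedFixture <- function(label, nx, ny, seed, dir,
                                  calib = defaultCalibration(),
                                  matrix = defaultTissueMatrix(),
                                  dwell = 5) {
  truth <- simulateMap(conditionProfile(label), nx = nx, ny = ny, seed = seed)
  fwd <- forwardXrf(truth, calib, matrix, dwell = dwell, seed = seed + 1L)
  specDir <- file.path(dir, "spectra")
  dir.create(specDir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(fwd$spectra)) {
    iy <- (p - 1L) %/% nx + 1L
    ix <- (p - 1L) %% nx + 1L
    writeSpectrum(fwd$spectra[[p]],
                  file.path(specDir, sprintf("pixel_%03d_%03d.txt", iy, ix)))
  }
  writeSpectrum(fwd$substrate, file.path(dir, "substrate.txt"))
  eff <- calib@efficiency
  yaml::write_yaml(list(
    incident_energy_keV = calib@incidentEnergy, flux_s1 = calib@flux,
    efficiency = list(energy_keV = as.list(eff[, 1]),
                      value = as.list(eff[, 2])),
    solid_angle_sr = calib@solidAngle,
    theta_in_deg = calib@thetaIn, theta_out_deg = calib@thetaOut,
    noise_fwhm_eV = calib@noiseFWHM, fano = calib@fano, w_eh_eV = calib@wEH
  ), file.path(dir, "calibration.yml"))
  for (el in elements(truth))
    utils::write.table(concentrations(truth, el),
                       file.path(dir, paste0("truth_C_", el, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  utils::write.table(thicknessField(truth),
                     file.path(dir, "truth_thickness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(
    package = "xrftir",
    version = as.character(utils::packageVersion("xrftir")),
    condition = label, nx = nx, ny = ny,
    seed_map = seed, seed_noise = seed + 1L, dwell_s = dwell,
    matrix = list(mass_fractions = as.list(matrix@massFractions),
                  density_g_cm3 = matrix@density)
  ), file.path(dir, "manifest.yml"))
  invisible(dir)
}
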