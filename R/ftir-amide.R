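#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an FTIR absorbance spectrum
#'
#' A descending wavenumber axis (the native ordering of many instrument
#' exports and JCAMP-DX files) is normalised to the internal strictly
#' increasing convention, values preserved.
#'
#' @param wavenumber wavenumber axis, 1/cm
#' @param absorbance absorbance, AU
#' @return an [FTIRSpectrum-class]
#' @export
ftirSpectrum <- function(wavenumber, absorbance) {
  if (length(wavenumber) > 1L && wavenumber[1] > wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  new("FTIRSpectrum", wavenumber = as.numeric(wavenumber),
      absorbance = as.numeric(absorbance))
}

#' @rdname wavenumbers
setMethod("wavenumbers", "FTIRSpectrum", function(object) object@wavenumber)

#' @rdname absorbance
setMethod("absorbance", "FTIRSpectrum", function(object) object@absorbance)

setMethod("show", "FTIRSpectrum", function(object) {
  w <- object@wavenumber
  cat(sprintf("FTIRSpectrum: %d points, %.0f-%.0f 1/cm, max absorbance %.4g AU\n",
              length(w), w[1], w[length(w)], max(object@absorbance)))
})

# linear interpolation of the spectrum at arbitrary wavenumbers
.specAt <- function(spec, w) {
  stats::approx(spec@wavenumber, spec@absorbance, xout = w)$y
}

#' Linear baseline correction anchored at a window's endpoints
#'
#' Subtracts the straight line through the spectrum values at the two window
#' endpoints; the corrected absorbance is exactly zero there. A single
#' shared baseline across the amide I + II region (default anchors 1480 and
#' 1720 1/cm) is the simplest reproducible treatment.
#'
#' @param spec an [FTIRSpectrum-class]
#' @param window numeric length-2, anchor wavenumbers (1/cm), inside the
#'   spectrum's range
#' @return a baseline-corrected [FTIRSpectrum-class] (full axis retained)
#' @export
baselineCorrect <- function(spec, window = c(1480, 1720)) {
  stopifnot(is(spec, "FTIRSpectrum"), length(window) == 2L)
  window <- sort(window)
  w <- spec@wavenumber
  if (window[1] < w[1] || window[2] > w[length(w)])
    stop("baseline window endpoints outside the spectrum axis")
  y1 <- .specAt(spec, window[1])
  y2 <- .specAt(spec, window[2])
  slope <- (y2 - y1) / (window[2] - window[1])
  base <- y1 + slope * (w - window[1])
  ftirSpectrum(w, spec@absorbance - base)
}

#' Pseudo-Voigt profile (unit-area parameterisation)
#'
#' \eqn{\eta} times a unit-area Lorentzian plus \eqn{(1-\eta)} times a
#' unit-area Gaussian, sharing centre and FWHM, scaled by `area`. The
#' analytic area of the profile equals `area` exactly.
#'
#' @param x evaluation points, 1/cm
#' @param area integrated area, AU/cm
#' @param center centre, 1/cm
#' @param fwhm full width at half maximum, 1/cm
#' @param eta Lorentzian mixing fraction in `[0, 1]`
#' @return profile values, AU
#' @export
pseudoVoigt <- function(x, area, center, fwhm, eta) {
  u <- (x - center) / fwhm
  g <- sqrt(4 * log(2) / pi) / fwhm * exp(-4 * log(2) * u^2)
  l <- 2 / (pi * fwhm) / (1 + 4 * u^2)
  area * (eta * l + (1 - eta) * g)
}

#' Integrated amide II band area
#'
#' Trapezoidal integral of the (baseline-corrected) absorbance over the
#' amide II window, with linear interpolation at the window ends.
#'
#' @param spec a baseline-corrected [FTIRSpectrum-class] covering the window
#' @param window integration window, 1/cm (default 1500-1580, centred on the
#'   1540 1/cm amide II band)
#' @return band area, AU/cm (non-negative values expected for real spectra)
#' @export
amideIIArea <- function(spec, window = c(1500, 1580)) {
  stopifnot(is(spec, "FTIRSpectrum"))
  window <- sort(window)
  w <- spec@wavenumber
  if (window[1] < w[1] || window[2] > w[length(w)])
    stop("amide II window not covered by the spectrum")
  inner <- w > window[1] & w < window[2]
  xs <- c(window[1], w[inner], window[2])
  ys <- c(.specAt(spec, window[1]), spec@absorbance[inner],
          .specAt(spec, window[2]))
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Default amide I component layout
#'
#' Five pseudo-Voigt components covering the named secondary structures:
#' two beta-sheet bands (~1630 and ~1690 1/cm, the anti-parallel pair),
#' random/unordered (~1650), alpha-helix (~1660) and beta-turn (~1678).
#' Centres are fixed at these canonical positions by default
#' (`centerTol = 0`): the heavily overlapped sub-bands make the
#' decomposition ill-posed when positions float, and pinning them is the
#' standard stabilisation in amide-band curve resolution. A positive
#' `centerTol` re-enables bounded centre refinement. FWHM is bounded to
#' `[10, 45]` 1/cm and the mixing `eta` to `[0, 1]` in the fit.
#'
#' @param centerTol centre bound half-width, 1/cm (0 = fixed positions)
#' @return data.frame of component definitions
#' @export
amideComponents <- function(centerTol = 0) {
  data.frame(
    assignment = c("beta_s", "random", "alpha", "beta_t", "beta_s"),
    center = c(1630, 1650, 1660, 1678, 1690),
    centerTol = centerTol,
    fwhmInit = c(28, 22, 22, 20, 15),
    stringsAsFactors = FALSE
  )
}

#' Fit the amide I band with constrained pseudo-Voigt components
#'
#' Constrained least squares of the five secondary-structure components of
#' [amideComponents()], fitted jointly with the amide II band over the
#' combined amide window (default 1480-1720 1/cm) so that the amide II wing
#' cannot bias the amide I components. The separable structure is exploited
#' (variable projection): for every trial of the nonlinear shape parameters
#' (FWHM in `[10, 45]` 1/cm, mixing `eta` in `[0, 1]`, centres fixed or
#' bounded per `components$centerTol`), the component areas are the exact
#' non-negative linear solution, and Levenberg-Marquardt iterates only the
#' shapes. The spectrum must be baseline corrected.
#'
#' When the spectrum covers the amide II integration window, its integrated
#' band area ([amideIIArea()]) is stored in the returned model so that
#' [structureRatios()] can be computed directly.
#'
#' @param spec a baseline-corrected [FTIRSpectrum-class] covering the fit
#'   window
#' @param components amide I component layout, see [amideComponents()]
#' @param window fit window, 1/cm; when it covers 1540 1/cm the amide II
#'   band (centre fixed at 1540, FWHM in `[20, 50]`) is included in the
#'   model
#' @param amideIIWindow integration window passed to [amideIIArea()]
#' @param sharedEta share one mixing parameter across all components
#'   (default; the per-band mixing of such overlapped bands is not
#'   identifiable at realistic noise) or fit one `eta` per component
#' @return an [AmideModel-class] (the fitted amide II band is carried as an
#'   `amide_II` row of the component table; it does not enter the ratios)
#' @export
fitAmideI <- function(spec, components = amideComponents(),
                      window = c(1480, 1720), amideIIWindow = c(1500, 1580),
                      sharedEta = TRUE) {
  stopifnot(is(spec, "FTIRSpectrum"))
  w <- spec@wavenumber
  if (window[1] < w[1] || window[2] > w[length(w)])
    stop("amide window not covered by the spectrum")
  idx <- w >= window[1] & w <= window[2]
  x <- w[idx]
  y <- spec@absorbance[idx]
  if (max(abs(y)) <= 0)
    stop("no amide signal: spectrum is zero over the amide window")
  fit <- .amideShapeFit(x, y, components, window, sharedEta)
  a2 <- if (amideIIWindow[1] >= w[1] && amideIIWindow[2] <= w[length(w)])
    amideIIArea(spec, amideIIWindow) else NA_real_
  new("AmideModel", components = fit$cmp,
      amideIIArea = a2,
      residualNorm = fit$rms,
      converged = fit$converged)
}

# core shape fit shared by fitAmideI and fitAmideEnsemble: variable
# projection over (FWHM, eta[, center]) with exact clipped-linear areas
.amideShapeFit <- function(x, y, components, window, sharedEta) {
  if (window[1] <= 1540 && window[2] >= 1540) {
    components <- rbind(components,
                        data.frame(assignment = "amide_II", center = 1540,
                                   centerTol = components$centerTol[1],
                                   fwhmInit = 34, stringsAsFactors = FALSE))
  }
  k <- nrow(components)
  fwLo <- ifelse(components$assignment == "amide_II", 20, 10)
  fwHi <- ifelse(components$assignment == "amide_II", 50, 45)
  freeCenter <- any(components$centerTol > 0)
  unpack <- function(p) {
    fw <- p[seq_len(k)]
    eta <- if (sharedEta) rep(p[k + 1], k) else p[k + seq_len(k)]
    nEta <- if (sharedEta) 1L else k
    cen <- if (freeCenter) p[k + nEta + seq_len(k)] else components$center
    list(fw = fw, eta = eta, cen = cen)
  }
  basis <- function(p) {
    q <- unpack(p)
    X <- vapply(seq_len(k), function(i)
      pseudoVoigt(x, 1, q$cen[i], q$fw[i], q$eta[i]), numeric(length(x)))
    matrix(X, nrow = length(x))
  }
  areasOf <- function(X) {
    a <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, k))
    a[!is.finite(a)] <- 0
    pmax(a, 0)
  }
  residFn <- function(p) {
    X <- basis(p)
    as.numeric(X %*% areasOf(X) - y)
  }
  par <- c(components$fwhmInit, rep(0.5, if (sharedEta) 1L else k))
  lower <- c(fwLo, rep(0, if (sharedEta) 1L else k))
  upper <- c(fwHi, rep(1, if (sharedEta) 1L else k))
  if (freeCenter) {
    par <- c(par, components$center)
    lower <- c(lower, components$center - components$centerTol)
    upper <- c(upper, components$center + components$centerTol)
  }
  fit <- minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper, fn = residFn,
    control = minpack.lm::nls.lm.control(maxiter = 400,
                                         ftol = 1e-13, ptol = 1e-13))
  q <- unpack(fit$par)
  X <- basis(fit$par)
  cmp <- data.frame(
    assignment = components$assignment,
    center = q$cen, fwhm = q$fw, eta = q$eta, area = areasOf(X),
    stringsAsFactors = FALSE
  )
  list(cmp = cmp, basisMatrix = X, rms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4)
}

#' Fit an ensemble of amide spectra with shapes calibrated on the mean
#'
#' Two-tier ensemble analysis: the pseudo-Voigt band shapes (FWHM, mixing)
#' are fitted once on the ensemble-mean spectrum -- where the counting noise
#' averages out -- and each individual spectrum is then decomposed by an
#' exact linear area solve at those fixed shapes. This removes the
#' noise-driven shape/area trade-off between the heavily overlapped amide I
#' sub-bands that inflates per-spectrum free fits, at the cost of assuming
#' the band shapes are common across the ensemble (the within-condition
#' assumption of the reporting unit).
#'
#' @param spectra list of [FTIRSpectrum-class] on a common axis
#' @param components amide I component layout, see [amideComponents()]
#' @param window joint fit window, 1/cm
#' @param amideIIWindow integration window for the ratio denominator
#' @param baseline apply [baselineCorrect()] (with `baselineWindow`) first
#' @param baselineWindow anchors for the baseline correction
#' @param sharedEta see [fitAmideI()]
#' @return list with `meanModel` (the [AmideModel-class] of the mean
#'   spectrum), `ratios` (matrix, one row of [structureRatios()] per
#'   spectrum) and `stats` (the [ensembleStats()] table)
#' @export
fitAmideEnsemble <- function(spectra, components = amideComponents(),
                             window = c(1480, 1720),
                             amideIIWindow = c(1500, 1580),
                             baseline = TRUE, baselineWindow = c(1480, 1720),
                             sharedEta = TRUE) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, is, logical(1), "FTIRSpectrum")))
  if (baseline)
    spectra <- lapply(spectra, baselineCorrect, window = baselineWindow)
  w <- spectra[[1]]@wavenumber
  for (s in spectra)
    if (!isTRUE(all.equal(s@wavenumber, w)))
      stop("ensemble spectra must share a common wavenumber axis")
  idx <- w >= window[1] & w <= window[2]
  x <- w[idx]
  Y <- vapply(spectra, function(s) s@absorbance[idx], numeric(sum(idx)))
  Y <- matrix(Y, nrow = sum(idx))
  fit <- .amideShapeFit(x, rowMeans(Y), components, window, sharedEta)
  a2mean <- amideIIArea(ftirSpectrum(w, rowMeans(vapply(
    spectra, absorbance, numeric(length(w))))), amideIIWindow)
  meanModel <- new("AmideModel", components = fit$cmp, amideIIArea = a2mean,
                   residualNorm = fit$rms, converged = fit$converged)
  qrX <- qr(fit$basisMatrix)
  assign <- fit$cmp$assignment
  groups <- c("beta_s", "alpha", "random", "beta_t")
  ratios <- t(vapply(seq_along(spectra), function(i) {
    a <- qr.coef(qrX, Y[, i])
    a[!is.finite(a)] <- 0
    a <- pmax(a, 0)
    a2 <- amideIIArea(spectra[[i]], amideIIWindow)
    r <- vapply(groups, function(g) sum(a[assign == g]) / a2, numeric(1))
    c(r, amide_I_total = sum(r))
  }, numeric(5)))
  list(meanModel = meanModel, ratios = ratios, stats = ensembleStats(ratios))
}

#' @rdname structureRatios
setMethod("structureRatios", "AmideModel", function(object) {
  a2 <- object@amideIIArea
  if (is.na(a2) || a2 <= 0)
    stop("amide II area unavailable or zero: ratios undefined")
  cmp <- object@components
  groups <- c("beta_s", "alpha", "random", "beta_t")
  r <- vapply(groups, function(g) sum(cmp$area[cmp$assignment == g]) / a2,
              numeric(1))
  c(r, amide_I_total = sum(r))
})

setMethod("show", "AmideModel", function(object) {
  cat("AmideModel:", nrow(object@components), "pseudo-Voigt components,",
      if (object@converged) "converged" else "NOT converged", "\n")
  print(object@components, digits = 4)
  cat(sprintf("  amide II area: %.4g AU/cm, rms residual %.3g AU\n",
              object@amideIIArea, object@residualNorm))
})

#' Ensemble statistics of secondary-structure ratios
#'
#' Arithmetic mean and sample standard deviation per ratio over an ensemble
#' of spectra (the per-condition reporting unit).
#'
#' @param ratios a list of named ratio vectors (as returned by
#'   [structureRatios()]) or a matrix with one row per spectrum
#' @return data.frame with columns `ratio`, `mean`, `sd`, `n`
#' @export
ensembleStats <- function(ratios) {
  if (is.list(ratios)) ratios <- do.call(rbind, ratios)
  if (is.null(dim(ratios)) || nrow(ratios) < 1L)
    stop("empty ratio ensemble")
  data.frame(
    ratio = colnames(ratios),
    mean = colMeans(ratios),
    sd = apply(ratios, 2, stats::sd),
    n = nrow(ratios),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Read an FTIR spectrum from two-column delimited text
#'
#' Columns: wavenumber (1/cm), absorbance (AU); comment lines start with
#' `#`. Descending axes are normalised.
#'
#' @param path file path
#' @return an [FTIRSpectrum-class]
#' @export
readFtirTable <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(tab) < 2L) stop("expected two columns: wavenumber, absorbance")
  ftirSpectrum(tab[[1]], tab[[2]])
}

#' Write an FTIR spectrum as two-column text
#' @param spec an [FTIRSpectrum-class]
#' @param path file path
#' @export
writeFtirTable <- function(spec, path) {
  utils::write.table(
    data.frame(wavenumber = sprintf("%.12g", spec@wavenumber),
               absorbance = sprintf("%.12g", spec@absorbance)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimal JCAMP-DX reader for infrared spectra
#'
#' Supports the AFFN `(X++(Y..Y))` tabular form and `(XY..XY)` point pairs
#' with `XFACTOR`/`YFACTOR`/`FIRSTX`/`LASTX`/`NPOINTS` scaling; compressed
#' (SQZ/DIF/DUP) ordinates are not supported. Descending axes are normalised
#' to the internal increasing convention.
#'
#' @param path file path
#' @return an [FTIRSpectrum-class]
#' @export
readJcamp <- function(path) {
  ln <- readLines(path, warn = FALSE)
  getLabel <- function(key) {
    m <- grep(paste0("^##", key, "="), ln, ignore.case = TRUE, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", m[1]))
  }
  num <- function(key, default = NA_real_) {
    v <- suppressWarnings(as.numeric(getLabel(key)))
    if (is.na(v)) default else v
  }
  xf <- num("XFACTOR", 1); yf <- num("YFACTOR", 1)
  start <- grep("^##XYDATA=|^##XYPOINTS=", ln, ignore.case = TRUE)
  if (!length(start)) stop("malformed JCAMP-DX: no XYDATA/XYPOINTS block")
  form <- toupper(ln[start[1]])
  end <- grep("^##", ln)
  end <- min(end[end > start[1]], length(ln) + 1L)
  body <- ln[(start[1] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body))))
    stop("compressed JCAMP-DX ordinate forms (SQZ/DIF/DUP) are not supported")
  if (grepl("XYPOINTS|\\(XY", form)) {
    vals <- as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+")))
    x <- vals[seq(1, length(vals), 2)] * xf
    y <- vals[seq(2, length(vals), 2)] * yf
  } else {
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); np <- num("NPOINTS")
    rows <- strsplit(trimws(body), "[,;[:space:]]+")
    y <- unlist(lapply(rows, function(r) as.numeric(r[-1])))
    if (!is.na(np) && length(y) != np)
      stop(sprintf("malformed JCAMP-DX: NPOINTS=%d but %d ordinates read",
                   np, length(y)))
    if (is.na(firstx) || is.na(lastx))
      stop("malformed JCAMP-DX: FIRSTX/LASTX required for (X++(Y..Y)) data")
    x <- seq(firstx, lastx, length.out = length(y)) * xf
    y <- y * yf
  }
  if (any(is.na(x)) || any(is.na(y)))
    stop("malformed JCAMP-DX: non-numeric data")
  ftirSpectrum(x, y)
}
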