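#' @include AllClasses.R AllGenerics.R
NULL

#' Two-sided Mann-Whitney-Wilcoxon comparison of two samples
#'
#' The U statistic is computed from rank sums with midranks for ties. The
#' two-sided p-value is exact (from the tie-free null distribution of U)
#' when `n_a * n_b <= 64` and the pooled sample has no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The exact branch refuses ties and falls through to the
#' approximation (concentrations are continuous, so ties are generator
#' artifacts).
#'
#' @param a,b numeric samples (both non-empty)
#' @param labelA,labelB group labels for the report row
#' @return one-row data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `U`
#'   (statistic of group a), `p` (two-sided), `annotation`
#'   (see [annotateSignificance()]) and `method` (`"exact"` or `"normal"`)
#' @examples
#' mannWhitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(a, b, labelA = "a", labelB = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled) # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (na * nb <= 64 && !ties) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        1 - stats::pwilcox(U - 1, na, nb)))
    method <- "exact"
  } else {
    N <- na + nb
    tj <- table(pooled)
    tieTerm <- sum(tj^3 - tj) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tieTerm)
    z <- max(0, abs(U - na * nb / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  data.frame(group_a = labelA, group_b = labelB, n_a = na, n_b = nb,
             U = U, p = p, annotation = annotateSignificance(p),
             method = method, stringsAsFactors = FALSE)
}

#' Significance annotation for a p-value
#'
#' The asterisk convention used throughout the reporting:
#' `ns` for p > 5e-2, `*` for 1e-2 < p <= 5e-2, `**` for 1e-3 < p <= 1e-2,
#' `***` for 1e-4 < p <= 1e-3 and `****` for p <= 1e-4.
#'
#' @param p p-value(s) in (0, 1]
#' @return character annotation(s)
#' @export
annotateSignificance <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  cut <- c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1)
  lab <- c("****", "***", "**", "*", "ns")
  lab[findInterval(p, cut, left.open = TRUE, rightmost.closed = TRUE)]
}

# extract the valid-pixel concentration vector for one element from either a
# ConcentrationMap or a named list of numeric vectors
.conditionValues <- function(x, element) {
  if (is(x, "ConcentrationMap")) {
    concentrations(x, element)[validMask(x)]
  } else if (is.list(x)) {
    v <- x[[element]]
    if (is.null(v)) stop("no values for element ", element)
    v
  } else stop("conditions must be ConcentrationMap objects or named lists")
}

#' Pairwise condition comparisons against a reference
#'
#' Compares each condition's valid-pixel concentration distribution against
#' the reference condition, per element, with [mannWhitney()]. No
#' multiple-testing correction is applied (per-pair annotations are
#' reported); the number of comparisons is attached as the attribute
#' `n_comparisons`.
#'
#' @param conditions named list of [ConcentrationMap-class] objects (or of
#'   named lists of per-element numeric vectors)
#' @param reference name of the reference condition (default `"PC"`)
#' @param elements element symbols to compare; default: the elements of the
#'   reference map
#' @return data.frame with one row per (element, condition pair):
#'   `element`, `group_a` (reference), `group_b`, `n_a`, `n_b`, `U`, `p`,
#'   `annotation`, `method`
#' @export
compareConditions <- function(conditions, reference = "PC", elements = NULL) {
  if (!reference %in% names(conditions))
    stop("reference condition '", reference, "' missing")
  others <- setdiff(names(conditions), reference)
  if (!length(others)) stop("need at least two conditions")
  ref <- conditions[[reference]]
  if (is.null(elements)) {
    elements <- if (is(ref, "ConcentrationMap")) ref@elements else names(ref)
  }
  rows <- list()
  for (el in elements) {
    va <- .conditionValues(ref, el)
    for (cond in others) {
      vb <- .conditionValues(conditions[[cond]], el)
      row <- mannWhitney(va, vb, labelA = reference, labelB = cond)
      rows[[length(rows) + 1L]] <- cbind(element = el, row,
                                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- nrow(out)
  out
}
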