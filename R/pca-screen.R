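#' Correlation-matrix PCA of a strain panel
#'
#' Projects strains (scores) and indicators (loadings) onto principal
#' components of the z-score standardized matrix. Standardization is
#' mandatory because indicators span incommensurate scales (percent, mg/L,
#' umol/L, mm); it makes the projection invariant to positive rescaling of
#' any column. The decomposition is the singular value decomposition of the
#' centered standardized matrix (via [stats::prcomp()]); component signs are
#' made deterministic by flipping each component so its largest-magnitude
#' loading is positive.
#'
#' @param x an [IndicatorMatrix-class] with at least 3 strains, at least 2
#'   indicators and no constant column, or a numeric matrix (strains in
#'   rows).
#' @param orientation benefit/cost per indicator when `x` is a bare matrix.
#' @param ... ignored.
#' @return A [PcaResult-class].
#' @examples
#' p <- pcaProject(table1Fixture())
#' varianceExplained(p)
#' @name pcaProject
#' @aliases pcaProject,IndicatorMatrix-method pcaProject,matrix-method
NULL

#' @rdname pcaProject
setMethod("pcaProject", "IndicatorMatrix", function(x, ...) {
  .pcaProject(indicatorValues(x), indicatorOrientation(x))
})

#' @rdname pcaProject
setMethod("pcaProject", "matrix", function(x, orientation = "benefit", ...) {
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("indicator", seq_len(ncol(x)))
  .pcaProject(x, setNames(rep_len(orientation, ncol(x)), nm))
})

.pcaProject <- function(v, orientation) {
  if (nrow(v) < 3L)
    .validationError("PCA screening needs at least 3 strains, got %d", nrow(v))
  if (ncol(v) < 2L)
    .validationError("PCA screening needs at least 2 indicators, got %d", ncol(v))
  if (anyNA(v) || any(!is.finite(v)))
    .validationError("matrix must be complete and finite for PCA")
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    .degenerateError("constant indicator(s) cannot be standardized: %s",
                     paste(colnames(v)[sds == 0], collapse = ", "))
  fit <- prcomp(v, center = TRUE, scale. = TRUE)
  scores <- fit$x
  loadings <- fit$rotation
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  new("PcaResult", scores = scores, loadings = loadings,
      varianceExplained = ve, orientation = orientation)
}

#' PcaResult accessors
#'
#' @param x a [PcaResult-class].
#' @return `strainScores()` and `indicatorLoadings()` return the score and
#'   loading matrices; `varianceExplained()` the per-component variance
#'   fractions.
#' @export
strainScores <- function(x) { stopifnot(is(x, "PcaResult")); x@scores }

#' @rdname strainScores
#' @export
indicatorLoadings <- function(x) { stopifnot(is(x, "PcaResult")); x@loadings }

#' @rdname strainScores
#' @export
varianceExplained <- function(x) { stopifnot(is(x, "PcaResult")); x@varianceExplained }

#' Quadrant of points in the PC1/PC2 plane
#'
#' Sign-convention quadrants: `(+, +)` is 1, `(-, +)` is 2, `(-, -)` is 3,
#' `(+, -)` is 4. Points exactly on an axis belong to no quadrant and get
#' `NA` — deterministic strictness beats floating-point ambiguity at the
#' boundary.
#'
#' @param xy two-column matrix of PC1/PC2 coordinates (or a length-2 vector).
#' @return Integer vector of quadrants (1–4 or `NA`).
#' @export
quadrantOf <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  stopifnot(ncol(xy) >= 2)
  x <- xy[, 1]; y <- xy[, 2]
  q <- rep(NA_integer_, length(x))
  q[x > 0 & y > 0] <- 1L
  q[x < 0 & y > 0] <- 2L
  q[x < 0 & y < 0] <- 3L
  q[x > 0 & y < 0] <- 4L
  q
}

#' Quadrant screen: strains co-located with the benefit indicators
#'
#' The biplot screening heuristic: find the PC1/PC2 quadrant holding the
#' largest number of benefit-indicator loadings and return the strains whose
#' scores fall in that quadrant. With the deterministic sign convention of
#' [pcaProject()] the benefit loadings concentrate in the `(+, +)` quadrant
#' for dominance-structured panels, so this reproduces the classical
#' "select quadrant 1" reading of a biplot while remaining valid under any
#' sign convention. Ties in the loading count are broken toward quadrant 1,
#' then toward the lowest quadrant number. Strains exactly on an axis are
#' never selected.
#'
#' @param p a [PcaResult-class].
#' @return Character vector of selected strain labels (possibly empty);
#'   attribute `"quadrant"` carries the winning quadrant.
#' @examples
#' quadrantSelect(pcaProject(table1Fixture()))
#' @export
quadrantSelect <- function(p) {
  stopifnot(is(p, "PcaResult"))
  benefit <- p@orientation == "benefit"
  lq <- quadrantOf(p@loadings[benefit, 1:2, drop = FALSE])
  counts <- tabulate(lq, nbins = 4L)
  top <- which(counts == max(counts))
  win <- if (1L %in% top) 1L else min(top)
  sq <- quadrantOf(p@scores[, 1:2, drop = FALSE])
  sel <- rownames(p@scores)[!is.na(sq) & sq == win]
  structure(sel, quadrant = win)
}
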