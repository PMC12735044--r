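#' Linear standard curve
#'
#' A fitted (or published) linear calibration `absorbance = slope *
#' concentration + intercept`, used to convert absorbance readings into
#' concentrations (glucose-equivalent exopolysaccharide, FeSO4-equivalent
#' reducing power, ...).
#'
#' @slot slope absorbance change per concentration unit; must be non-zero.
#' @slot intercept absorbance at zero concentration.
#' @slot rSquared squared Pearson correlation of the calibration points in
#'   `[0, 1]`, or `NA` when unknown (e.g. a published curve).
#' @slot unit text label of the concentration unit, e.g. `"mg/L"`.
#'
#' @seealso [fitStandardCurve()], [invertStandardCurve()]
#' @exportClass LinearStandardCurve
setClass("LinearStandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", unit = "character"))

setValidity("LinearStandardCurve", function(object) {
  msg <- NULL
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope == 0)
    msg <- c(msg, "slope must be a single finite non-zero number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  r2 <- object@rSquared
  if (length(r2) != 1L || (!is.na(r2) && (r2 < 0 || r2 > 1)))
    msg <- c(msg, "rSquared must lie in [0, 1] (or be NA)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a linear standard curve
#'
#' @param slope,intercept line coefficients on the absorbance scale.
#' @param rSquared optional goodness-of-fit (squared Pearson correlation).
#' @param unit concentration unit label.
#' @return A [LinearStandardCurve-class] object.
#' @examples
#' linearStandardCurve(0.0039, 0.0033, rSquared = 0.9994, unit = "mg/L")
#' @export
linearStandardCurve <- function(slope, intercept, rSquared = NA_real_,
                                unit = "") {
  new("LinearStandardCurve", slope = as.numeric(slope),
      intercept = as.numeric(intercept), rSquared = as.numeric(rSquared),
      unit = as.character(unit))
}

setMethod("show", "LinearStandardCurve", function(object) {
  cat(sprintf("LinearStandardCurve: absorbance = %g * x + %g\n",
              object@slope, object@intercept))
  cat(sprintf("  unit: %s   R^2: %s\n",
              if (nzchar(object@unit)) object@unit else "<unset>",
              ifelse(is.na(object@rSquared), "NA",
                     format(object@rSquared, digits = 4))))
})

#' Strain-by-indicator decision matrix
#'
#' The central container of the package: a matrix of per-strain indicator
#' means (optionally with replicate standard deviations) plus a per-indicator
#' benefit/cost orientation. It extends
#' [SummarizedExperiment::SummarizedExperiment] with indicators as rows
#' (features, carrying `orientation` and `unit` in `rowData`) and strains as
#' columns (samples), so the usual Bioconductor subsetting and metadata
#' machinery apply. User-facing accessors present the matrix in the
#' strains-by-indicators orientation used for ranking.
#'
#' Validity requires at least one strain and one indicator, unique labels,
#' no infinite values, and orientations in `benefit`/`cost`. At least two
#' strains and complete (non-missing) values are additionally required by
#' the ranking functions, not by the container.
#'
#' @seealso [IndicatorMatrix()], [buildIndicatorMatrix()],
#'   [indicatorValues()], [entropyWeights()], [topsisScores()]
#' @exportClass IndicatorMatrix
setClass("IndicatorMatrix", contains = "SummarizedExperiment")

setValidity("IndicatorMatrix", function(object) {
  msg <- NULL
  if (nrow(object) < 1L) msg <- c(msg, "at least one indicator is required")
  if (ncol(object) < 1L) msg <- c(msg, "at least one strain is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "indicator names must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "strain labels must be unique")
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  else {
    v <- SummarizedExperiment::assay(object, "values")
    if (any(is.infinite(v))) msg <- c(msg, "indicator values must be finite")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"orientation" %in% colnames(rd))
    msg <- c(msg, "rowData column 'orientation' is required")
  else if (!all(rd$orientation %in% c("benefit", "cost")))
    msg <- c(msg, "orientation must be 'benefit' or 'cost'")
  if (is.null(msg)) TRUE else msg
})

#' Entropy-derived indicator weights
#'
#' Per-indicator Shannon entropy `Ej`, information utility `Dj = 1 - Ej`,
#' and normalized weight `Wj = Dj / sum(Dj)` computed from the
#' column-proportion matrix of an [IndicatorMatrix-class].
#'
#' @slot entropy named numeric, `Ej` in `[0, 1]`.
#' @slot utility named numeric, `Dj = 1 - Ej`.
#' @slot weight named numeric, non-negative and summing to one.
#' @seealso [entropyWeights()]
#' @exportClass EntropyWeights
setClass("EntropyWeights",
         representation(entropy = "numeric", utility = "numeric",
                        weight = "numeric"))

setValidity("EntropyWeights", function(object) {
  msg <- NULL
  n <- length(object@entropy)
  if (length(object@utility) != n || length(object@weight) != n)
    msg <- c(msg, "entropy, utility and weight must have equal length")
  if (any(abs(object@utility - (1 - object@entropy)) > 1e-12))
    msg <- c(msg, "utility must equal 1 - entropy")
  if (any(object@weight < 0)) msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weight) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "EntropyWeights", function(object) {
  cat(sprintf("EntropyWeights over %d indicators\n", length(object@weight)))
  df <- data.frame(Ej = object@entropy, Dj = object@utility,
                   Wj = sprintf("%.2f%%", 100 * object@weight),
                   row.names = names(object@weight))
  print(format(df, digits = 4))
})

#' TOPSIS closeness scores
#'
#' Per-strain Euclidean distances to the ideal-best (`D+`) and ideal-worst
#' (`D-`) weighted-normalized points, the relative closeness
#' `Ci = D- / (D+ + D-)`, and the resulting competition rank (1 = best,
#' ties share the best rank).
#'
#' @slot dPlus named numeric, distance to the ideal-best point.
#' @slot dMinus named numeric, distance to the ideal-worst point.
#' @slot closeness named numeric in `[0, 1]`.
#' @slot rank named integer, a (tie-aware) ranking of the strains.
#' @seealso [topsisScores()], [rankStrains()], [closeness()]
#' @exportClass TopsisScores
setClass("TopsisScores",
         representation(dPlus = "numeric", dMinus = "numeric",
                        closeness = "numeric", rank = "integer"))

setValidity("TopsisScores", function(object) {
  msg <- NULL
  n <- length(object@closeness)
  if (length(object@dPlus) != n || length(object@dMinus) != n ||
      length(object@rank) != n)
    msg <- c(msg, "all slots must have equal length")
  if (any(object@dPlus < 0) || any(object@dMinus < 0))
    msg <- c(msg, "distances must be non-negative")
  if (any(object@closeness < -1e-12 | object@closeness > 1 + 1e-12))
    msg <- c(msg, "closeness must lie in [0, 1]")
  if (n > 0 && min(object@rank) != 1L)
    msg <- c(msg, "best rank must be 1")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "TopsisScores", function(object) {
  cat(sprintf("TopsisScores for %d strains\n", length(object@closeness)))
  print(rankStrains(object))
})

#' Principal-component projection of a strain panel
#'
#' Scores (strains) and loadings (indicators) of a correlation-matrix PCA of
#' an [IndicatorMatrix-class], with the per-component fraction of variance
#' explained. Signs are made deterministic by forcing the largest-magnitude
#' loading of each component to be positive. The indicator orientations are
#' carried along so the quadrant screen can count benefit indicators.
#'
#' @slot scores strains x components score matrix.
#' @slot loadings indicators x components loading (rotation) matrix.
#' @slot varianceExplained fraction of total variance per component; sums
#'   to one over the full set of returned components.
#' @slot orientation named character, benefit/cost per indicator.
#' @seealso [pcaProject()], [quadrantSelect()], [quadrantOf()]
#' @exportClass PcaResult
setClass("PcaResult",
         representation(scores = "matrix", loadings = "matrix",
                        varianceExplained = "numeric",
                        orientation = "character"))

setValidity("PcaResult", function(object) {
  msg <- NULL
  ve <- object@varianceExplained
  if (any(ve < -1e-12 | ve > 1 + 1e-12))
    msg <- c(msg, "variance fractions must lie in [0, 1]")
  if (abs(sum(ve) - 1) > 1e-8)
    msg <- c(msg, "variance fractions must sum to 1")
  if (ncol(object@scores) != ncol(object@loadings))
    msg <- c(msg, "scores and loadings must agree on component count")
  if (length(object@orientation) != nrow(object@loadings))
    msg <- c(msg, "one orientation per indicator is required")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PcaResult", function(object) {
  ve <- object@varianceExplained
  cat(sprintf("PcaResult: %d strains x %d indicators\n",
              nrow(object@scores), nrow(object@loadings)))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance (%d components)\n",
              100 * ve[1], if (length(ve) > 1) 100 * ve[2] else 0,
              length(ve)))
})
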