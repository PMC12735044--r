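#' Shannon entropy weights for a decision matrix
#'
#' Objective per-indicator weights from the information content of the
#' strain-by-indicator matrix. For each indicator `j`, the column is turned
#' into proportions `p_ij = x_ij / sum_i x_ij`, the normalized Shannon
#' entropy is
#' `E_j = -(1/ln n) * sum_i p_ij ln p_ij` (with `0 ln 0 := 0`), the
#' information utility is `D_j = 1 - E_j`, and the weight is
#' `W_j = D_j / sum_j D_j`. An indicator on which all strains agree carries
#' no information (`E_j = 1`, weight 0); an indicator concentrated on few
#' strains carries much.
#'
#' The matrix must be strictly positive — apply [shiftPositive()] first if
#' any indicator can be zero or negative.
#'
#' @param x an [IndicatorMatrix-class] or a strictly positive numeric matrix
#'   (strains in rows).
#' @param ... ignored.
#' @return An [EntropyWeights-class].
#' @examples
#' m <- table1Fixture()
#' entropyWeights(m)
#' @name entropyWeights
#' @aliases entropyWeights,IndicatorMatrix-method entropyWeights,matrix-method
NULL

#' @rdname entropyWeights
setMethod("entropyWeights", "IndicatorMatrix", function(x, ...) {
  entropyWeights(indicatorValues(x))
})

#' @rdname entropyWeights
setMethod("entropyWeights", "matrix", function(x, ...) {
  if (nrow(x) < 2L)
    .validationError("entropy weighting needs at least 2 strains, got %d", nrow(x))
  if (anyNA(x) || any(!is.finite(x)))
    .validationError("matrix must be complete and finite for weighting")
  if (any(x <= 0))
    .validationError("matrix must be strictly positive; apply shiftPositive() first")
  n <- nrow(x)
  p <- sweep(x, 2, colSums(x), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  ej <- -colSums(plogp) / log(n)
  # guard tiny negative/overshoot from floating point
  ej <- pmin(pmax(ej, 0), 1)
  dj <- 1 - ej
  if (all(dj == 0))
    .degenerateError("every indicator is constant across strains; weights are undefined")
  wj <- dj / sum(dj)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("indicator", seq_along(ej))
  new("EntropyWeights", entropy = setNames(ej, nm),
      utility = setNames(dj, nm), weight = setNames(wj, nm))
})

#' Relative closeness to the ideal solution
#'
#' `Ci = D- / (D+ + D-)` for non-negative distances to the ideal-best and
#' ideal-worst points. `Ci = 1` at the ideal best (`D+ = 0`), `Ci = 0` at
#' the ideal worst (`D- = 0`).
#'
#' @param dPlus,dMinus non-negative distances (vectorized).
#' @return Closeness values in `[0, 1]`.
#' @examples
#' closeness(0.406, 0.597)  # 0.595 to 3 decimals
#' @export
closeness <- function(dPlus, dMinus) {
  n <- max(length(dPlus), length(dMinus))
  dPlus <- rep_len(as.numeric(dPlus), n)
  dMinus <- rep_len(as.numeric(dMinus), n)
  if (any(!is.finite(dPlus)) || any(!is.finite(dMinus)) ||
      any(dPlus < 0) || any(dMinus < 0))
    .validationError("distances must be finite and non-negative")
  if (any(dPlus + dMinus == 0))
    .degenerateError("D+ and D- are both zero; closeness is undefined (identical strains)")
  dMinus / (dPlus + dMinus)
}

#' TOPSIS scores of a weighted decision matrix
#'
#' Ranks strains by similarity to the ideal solution: each indicator column
#' is vector-normalized (`r_ij = x_ij / sqrt(sum_i x_ij^2)`), scaled by its
#' weight (`v_ij = W_j r_ij`), the ideal-best point takes the per-column
#' maximum of `v` on benefit indicators (minimum on cost) and the
#' ideal-worst point the mirror image, and each strain's Euclidean distances
#' `D+` / `D-` to those two points give the relative closeness
#' `Ci = D- / (D+ + D-)`. Higher `Ci` is better; ranks are competition ranks
#' on descending `Ci`.
#'
#' If all strains are identical every `D+ = D- = 0`; by convention all `Ci`
#' are then 0.5 with tied ranks.
#'
#' @param x an [IndicatorMatrix-class] (orientations taken from the object)
#'   or a positive numeric matrix, strains in rows.
#' @param weights an [EntropyWeights-class] or a non-negative numeric vector
#'   summing to 1, one weight per indicator. Defaults to entropy weights
#'   computed from `x`.
#' @param orientation benefit/cost per indicator when `x` is a bare matrix.
#' @param ... ignored.
#' @return A [TopsisScores-class].
#' @examples
#' m <- table1Fixture()
#' topsisScores(m, entropyWeights(m))
#' @name topsisScores
#' @aliases topsisScores,IndicatorMatrix,ANY-method topsisScores,matrix,ANY-method
NULL

#' @rdname topsisScores
setMethod("topsisScores", signature(x = "IndicatorMatrix"),
          function(x, weights, ...) {
  if (missing(weights)) weights <- entropyWeights(x)
  .topsis(indicatorValues(x), weights, indicatorOrientation(x))
})

#' @rdname topsisScores
setMethod("topsisScores", signature(x = "matrix"),
          function(x, weights, orientation = "benefit", ...) {
  if (missing(weights)) weights <- entropyWeights(x)
  .topsis(x, weights, rep_len(orientation, ncol(x)))
})

.topsis <- function(x, weights, orientation) {
  if (is(weights, "EntropyWeights")) weights <- weights@weight
  weights <- as.numeric(weights)
  if (length(weights) != ncol(x))
    .validationError("need one weight per indicator: %d weights for %d indicators",
                     length(weights), ncol(x))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    .validationError("weights must be non-negative and sum to 1")
  if (nrow(x) < 2L)
    .validationError("ranking needs at least 2 strains, got %d", nrow(x))
  if (anyNA(x) || any(!is.finite(x)))
    .validationError("matrix must be complete and finite for ranking")
  if (any(x <= 0))
    .validationError("matrix must be strictly positive; apply shiftPositive() first")

  norms <- sqrt(colSums(x^2))
  r <- sweep(x, 2, norms, "/")
  v <- sweep(r, 2, weights, "*")
  benefit <- orientation == "benefit"
  best <- ifelse(benefit, apply(v, 2, max), apply(v, 2, min))
  worst <- ifelse(benefit, apply(v, 2, min), apply(v, 2, max))
  dplus <- sqrt(rowSums(sweep(v, 2, best)^2))
  dminus <- sqrt(rowSums(sweep(v, 2, worst)^2))
  tot <- dplus + dminus
  ci <- ifelse(tot > 0, dminus / tot, 0.5)
  nm <- rownames(x)
  if (is.null(nm)) nm <- paste0("strain", seq_len(nrow(x)))
  new("TopsisScores",
      dPlus = setNames(dplus, nm), dMinus = setNames(dminus, nm),
      closeness = setNames(ci, nm),
      rank = setNames(as.integer(rank(-ci, ties.method = "min")), nm))
}

#' Ordered ranking report
#'
#' Tabulates TOPSIS scores sorted by descending closeness. Ties share the
#' best (minimum) rank — competition ranking — and tied strains are listed
#' lexicographically by label so the report is fully deterministic.
#'
#' @param x a [TopsisScores-class], or a named numeric vector of closeness
#'   values (distances are then reported as `NA`).
#' @param digits decimal places for the display columns (full-precision
#'   closeness is kept in the `ci` column); default 3.
#' @param ... ignored.
#' @return data.frame with columns `strain`, `d_plus`, `d_minus`, `ci`,
#'   `ci_display`, `rank`, ordered best first.
#' @name rankStrains
#' @aliases rankStrains,TopsisScores-method rankStrains,numeric-method
NULL

#' @rdname rankStrains
setMethod("rankStrains", "TopsisScores", function(x, digits = 3, ...) {
  .rankReport(x@closeness, x@dPlus, x@dMinus, digits)
})

#' @rdname rankStrains
setMethod("rankStrains", "numeric", function(x, digits = 3, ...) {
  if (is.null(names(x)))
    names(x) <- paste0("strain", seq_along(x))
  .rankReport(x, setNames(rep(NA_real_, length(x)), names(x)),
              setNames(rep(NA_real_, length(x)), names(x)), digits)
})

.rankReport <- function(ci, dplus, dminus, digits) {
  rk <- as.integer(rank(-ci, ties.method = "min"))
  ord <- order(-ci, names(ci), method = "radix")
  data.frame(strain = names(ci)[ord],
             d_plus = round(unname(dplus)[ord], digits),
             d_minus = round(unname(dminus)[ord], digits),
             ci = unname(ci)[ord],
             ci_display = round(unname(ci)[ord], digits),
             rank = rk[ord],
             row.names = NULL)
}
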