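#' Run the full screening pipeline
#'
#' One call from decision matrix to report: positivity shift, entropy
#' weighting, TOPSIS ranking, PCA quadrant screen, and an agreement flag
#' saying whether the TOPSIS rank-1 strain is among the strains the quadrant
#' screen selects. The report is fully deterministic for a given matrix and
#' configuration and embeds both full-precision and display-rounded values,
#' so downstream consumers never depend on rounding.
#'
#' @param x an [IndicatorMatrix-class], or the path of a matrix CSV in the
#'   [readIndicatorMatrix()] dialect.
#' @param orientation per-indicator benefit/cost used when `x` is a path.
#' @param weights `"entropy"` (default) or a numeric weight vector summing
#'   to 1.
#' @param epsilon positivity-shift margin passed to [shiftPositive()].
#' @param digits display rounding for the report tables, default 3.
#' @param pca run the PCA quadrant screen (needs >= 3 strains)? Default
#'   `TRUE`.
#' @return A list of class `ScreeningReport` with elements `provenance`
#'   (package version, dimensions, labels, content digest, config echo),
#'   `weights`, `scores`, `ranking` (ordered data.frame), `pca`
#'   (variance fractions, selection, winning quadrant; `NULL` when
#'   disabled) and `agreement`.
#' @examples
#' rep <- runPipeline(table1Fixture())
#' rep$ranking
#' @export
runPipeline <- function(x, orientation = "benefit", weights = "entropy",
                        epsilon = 1e-6, digits = 3, pca = TRUE) {
  if (is.character(x) && length(x) == 1L)
    x <- readIndicatorMatrix(x, orientation = orientation)
  if (!is(x, "IndicatorMatrix"))
    .validationError("x must be an IndicatorMatrix or a CSV path")
  validObject(x)
  if (digits < 0) .validationError("digits must be non-negative")
  if (epsilon <= 0) .validationError("epsilon must be positive")

  xs <- shiftPositive(x, epsilon)
  if (identical(weights, "entropy")) {
    w <- entropyWeights(xs)
    ej <- as.list(w@entropy); dj <- as.list(w@utility)
    wj <- setNames(as.numeric(w@weight), names(w@weight))
  } else {
    wj <- setNames(rep_len(as.numeric(weights), nrow(x)), rownames(x))
    ej <- NULL; dj <- NULL
    w <- wj
  }
  sc <- topsisScores(xs, w)
  ranking <- rankStrains(sc, digits = digits)

  pca_block <- NULL
  if (isTRUE(pca)) {
    pr <- pcaProject(x)
    sel <- quadrantSelect(pr)
    pca_block <- list(varianceExplained = unname(pr@varianceExplained),
                      selected = as.character(sel),
                      quadrant = attr(sel, "quadrant"))
  }
  top1 <- ranking$strain[1]
  agreement <- if (is.null(pca_block)) NA else top1 %in% pca_block$selected

  v <- indicatorValues(x)
  structure(list(
    provenance = list(
      tool = "StrainScreen",
      version = as.character(packageVersion("StrainScreen")),
      nStrains = nrow(v), nIndicators = ncol(v),
      strains = rownames(v), indicators = colnames(v),
      matrixDigest = .contentDigest(v),
      config = list(weights = if (identical(weights, "entropy")) "entropy"
                              else "user-supplied",
                    epsilon = epsilon, digits = digits, pca = isTRUE(pca))),
    weights = list(entropy = ej,
                   utility = dj,
                   weight = as.list(wj),
                   weight_display = as.list(round(wj, digits + 1))),
    scores = list(d_plus = as.list(sc@dPlus),
                  d_minus = as.list(sc@dMinus),
                  ci = as.list(sc@closeness),
                  rank = as.list(sc@rank)),
    ranking = ranking,
    pca = pca_block,
    agreement = agreement),
    class = "ScreeningReport")
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat(sprintf("ScreeningReport (%s %s): %d strains x %d indicators\n",
              x$provenance$tool, x$provenance$version,
              x$provenance$nStrains, x$provenance$nIndicators))
  print(x$ranking)
  if (!is.null(x$pca)) {
    cat(sprintf("PCA quadrant %d selection: %s\n", x$pca$quadrant,
                paste(x$pca$selected, collapse = ", ")))
    cat(sprintf("TOPSIS / PCA agreement: %s\n", x$agreement))
  }
  invisible(x)
}

#' Write a screening report as JSON
#'
#' Serializes a [runPipeline()] report deterministically (no timestamps):
#' two runs on the same inputs produce byte-identical files.
#'
#' @param report a `ScreeningReport`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeScreeningReport <- function(report, path) {
  stopifnot(inherits(report, "ScreeningReport"))
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
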