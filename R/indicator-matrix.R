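#' Construct an IndicatorMatrix from a strains-by-indicators matrix
#'
#' @param values numeric matrix or data.frame, strains in rows (rownames or
#'   `strains` give the labels), indicators in columns.
#' @param sds optional matrix of replicate standard deviations, same shape.
#' @param orientation per-indicator `"benefit"` (higher is better) or
#'   `"cost"`; a scalar is recycled. All indicators of the packaged
#'   antioxidant/production/antibacterial panel are benefit-type.
#' @param units optional per-indicator unit labels.
#' @param strains,indicators optional label vectors overriding dimnames.
#' @return An [IndicatorMatrix-class].
#' @examples
#' m <- IndicatorMatrix(matrix(1:6, 2, 3,
#'        dimnames = list(c("A", "B"), c("x", "y", "z"))))
#' indicatorValues(m)
#' @export
IndicatorMatrix <- function(values, sds = NULL, orientation = "benefit",
                            units = NULL, strains = NULL, indicators = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(strains)) rownames(values) <- strains
  if (!is.null(indicators)) colnames(values) <- indicators
  if (is.null(rownames(values)))
    rownames(values) <- paste0("strain", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("indicator", seq_len(ncol(values)))
  orientation <- rep_len(as.character(orientation), ncol(values))
  units <- rep_len(if (is.null(units)) "" else as.character(units), ncol(values))
  assays <- list(values = t(values))
  if (!is.null(sds)) {
    sds <- as.matrix(sds)
    storage.mode(sds) <- "double"
    if (!all(dim(sds) == dim(values)))
      .validationError("sds must have the same shape as values")
    dimnames(sds) <- dimnames(values)
    assays$sd <- t(sds)
  }
  rd <- S4Vectors::DataFrame(orientation = orientation, unit = units,
                             row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, rowData = rd)
  new("IndicatorMatrix", se)
}

#' Accessors for IndicatorMatrix objects
#'
#' `indicatorValues()` returns the strains-by-indicators matrix of means,
#' `indicatorSds()` the matching standard deviations (or `NULL`),
#' `strainNames()` / `indicatorNames()` the labels, and
#' `indicatorOrientation()` the named benefit/cost vector.
#'
#' @param x an [IndicatorMatrix-class].
#' @param ... ignored.
#' @return See description; matrices are strains x indicators.
#' @name indicatorValues
#' @aliases indicatorValues,IndicatorMatrix-method
#'   indicatorSds,IndicatorMatrix-method strainNames,IndicatorMatrix-method
#'   indicatorNames,IndicatorMatrix-method
#'   indicatorOrientation,IndicatorMatrix-method
NULL

#' @rdname indicatorValues
setMethod("indicatorValues", "IndicatorMatrix", function(x, ...) {
  t(SummarizedExperiment::assay(x, "values"))
})

#' @rdname indicatorValues
setMethod("indicatorSds", "IndicatorMatrix", function(x, ...) {
  if (!"sd" %in% SummarizedExperiment::assayNames(x)) return(NULL)
  t(SummarizedExperiment::assay(x, "sd"))
})

#' @rdname indicatorValues
setMethod("strainNames", "IndicatorMatrix", function(x) colnames(x))

#' @rdname indicatorValues
setMethod("indicatorNames", "IndicatorMatrix", function(x) rownames(x))

#' @rdname indicatorValues
setMethod("indicatorOrientation", "IndicatorMatrix", function(x) {
  setNames(as.character(SummarizedExperiment::rowData(x)$orientation),
           rownames(x))
})

setMethod("show", "IndicatorMatrix", function(object) {
  cat(sprintf("IndicatorMatrix: %d strains x %d indicators\n",
              ncol(object), nrow(object)))
  orient <- indicatorOrientation(object)
  cat("  indicators:",
      paste0(names(orient), ifelse(orient == "cost", " (cost)", ""),
             collapse = ", "), "\n")
  cat("  strains:", paste(colnames(object), collapse = ", "), "\n")
  if ("sd" %in% SummarizedExperiment::assayNames(object))
    cat("  replicate SDs: present\n")
})

#' Assemble an IndicatorMatrix from tidy per-strain records
#'
#' Builds the decision matrix from long-format rows with columns `strain`,
#' `indicator` and `value` (plus optional `replicate`; replicates are reduced
#' by arithmetic mean with the SD kept alongside). Row order follows the
#' first appearance of each strain, column order the declared (or first
#' appearance) indicator order, so the result is invariant to shuffling the
#' input rows. Duplicate or missing (strain, indicator) cells are a hard
#' error listing the offending pairs — with panels this small, silent
#' imputation would be worse than failure.
#'
#' @param records data.frame with the columns above.
#' @param indicators optional character vector fixing the indicator order.
#' @param strains optional character vector fixing the strain order.
#' @param orientation per-indicator benefit/cost (scalar recycled).
#' @param units optional unit labels.
#' @return An [IndicatorMatrix-class].
#' @export
buildIndicatorMatrix <- function(records, indicators = NULL, strains = NULL,
                                 orientation = "benefit", units = NULL) {
  needed <- c("strain", "indicator", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    .validationError("records lack column(s): %s",
                     paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L)
    .validationError("no records supplied")
  records$strain <- as.character(records$strain)
  records$indicator <- as.character(records$indicator)
  if (is.null(strains)) strains <- unique(records$strain)
  if (is.null(indicators)) indicators <- unique(records$indicator)
  unknown <- setdiff(records$strain, strains)
  if (length(unknown))
    .validationError("records contain undeclared strain(s): %s",
                     paste(unknown, collapse = ", "))
  unknown <- setdiff(records$indicator, indicators)
  if (length(unknown))
    .validationError("records contain undeclared indicator(s): %s",
                     paste(unknown, collapse = ", "))

  has_rep <- "replicate" %in% names(records)
  if (has_rep) {
    repkey <- paste(records$strain, records$indicator, records$replicate, sep = "\r")
    dup <- duplicated(repkey)
    if (any(dup))
      .validationError("duplicate replicate cell(s): %s",
                       paste(unique(paste0("(", records$strain[dup], ", ",
                                           records$indicator[dup], ", rep ",
                                           records$replicate[dup], ")")),
                             collapse = ", "))
  } else {
    cellkey <- paste(records$strain, records$indicator, sep = "\r")
    dup <- duplicated(cellkey)
    if (any(dup))
      .validationError("duplicate cell(s): %s",
                       paste(unique(paste0("(", records$strain[dup], ", ",
                                           records$indicator[dup], ")")),
                             collapse = ", "))
  }

  vals <- matrix(NA_real_, length(strains), length(indicators),
                 dimnames = list(strains, indicators))
  sds <- vals
  cell <- split(records$value,
                list(factor(records$strain, strains),
                     factor(records$indicator, indicators)), sep = "\r")
  for (nm in names(cell)) {
    v <- cell[[nm]]
    if (!length(v)) next
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    vals[parts[1], parts[2]] <- mean(v)
    sds[parts[1], parts[2]] <- if (length(v) > 1) sd(v) else NA_real_
  }
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)
    .validationError("missing cell(s): %s",
                     paste(paste0("(", strains[idx[, 1]], ", ",
                                  indicators[idx[, 2]], ")"), collapse = ", "))
  }
  IndicatorMatrix(vals, sds = if (all(is.na(sds))) NULL else sds,
                  orientation = orientation, units = units)
}

#' Column extrema of an indicator
#'
#' Exact minimum, maximum or range of one indicator's per-strain means —
#' the summaries quoted when describing a panel (e.g. "chelation ranged from
#' 23.98% to 54.70%").
#'
#' @param x an [IndicatorMatrix-class].
#' @param indicator indicator name.
#' @param stat one of `"min"`, `"max"`, `"range"` (max minus min).
#' @return A single number.
#' @name columnSummary
#' @aliases columnSummary,IndicatorMatrix-method
NULL

#' @rdname columnSummary
setMethod("columnSummary", "IndicatorMatrix",
          function(x, indicator, stat = c("min", "max", "range")) {
  stat <- match.arg(stat)
  if (!indicator %in% rownames(x))
    .validationError("unknown indicator '%s'; available: %s", indicator,
                     paste(rownames(x), collapse = ", "))
  v <- indicatorValues(x)[, indicator]
  if (anyNA(v))
    .validationError("indicator '%s' has missing values", indicator)
  switch(stat, min = min(v), max = max(v), range = max(v) - min(v))
})

#' Shift columns to strict positivity
#'
#' Entropy weighting needs strictly positive proportions. Columns containing
#' any value <= 0 are shifted by `-min + epsilon`; all-positive columns are
#' returned bit-identical. With `epsilon = 0` a zero minimum survives the
#' shift; the result is then flagged entropy-unsafe (`0 * log 0` terms are
#' handled, but a zero proportion still degrades the entropy estimate) and a
#' warning is raised.
#'
#' @param x an [IndicatorMatrix-class].
#' @param epsilon small positive shift margin, default `1e-6`.
#' @return A shifted [IndicatorMatrix-class]; `metadata(x)$entropyUnsafe` is
#'   `TRUE` when zeros remain.
#' @name shiftPositive
#' @aliases shiftPositive,IndicatorMatrix-method
NULL

#' @rdname shiftPositive
setMethod("shiftPositive", "IndicatorMatrix", function(x, epsilon = 1e-6) {
  if (epsilon < 0) .validationError("epsilon must be non-negative")
  v <- indicatorValues(x)
  if (anyNA(v)) .validationError("matrix has missing values")
  shifted <- v
  for (j in seq_len(ncol(v))) {
    if (any(v[, j] <= 0)) shifted[, j] <- v[, j] - min(v[, j]) + epsilon
  }
  out <- x
  SummarizedExperiment::assay(out, "values") <- t(shifted)
  if (any(shifted <= 0)) {
    S4Vectors::metadata(out)$entropyUnsafe <- TRUE
    warning("zeros remain after shifting (epsilon = 0); entropy weighting is unsafe")
  }
  out
})

#' Read / write the indicator-matrix CSV dialect
#'
#' The interchange format is one row per strain: a leading `strain` column,
#' one column per indicator, and optional `<indicator>_sd` columns with the
#' replicate standard deviations.
#'
#' @param path CSV file path.
#' @param orientation per-indicator benefit/cost for [readIndicatorMatrix()]
#'   (scalar recycled, or a named vector covering all indicators).
#' @param x an [IndicatorMatrix-class] for [writeIndicatorMatrix()].
#' @return [readIndicatorMatrix()] returns an [IndicatorMatrix-class];
#'   [writeIndicatorMatrix()] invisibly returns `path`.
#' @export
readIndicatorMatrix <- function(path, orientation = "benefit") {
  df <- read.csv(path, check.names = FALSE)
  if (!"strain" %in% names(df))
    .validationError("matrix CSV must have a 'strain' column")
  cols <- setdiff(names(df), "strain")
  sd_cols <- grep("_sd$", cols, value = TRUE)
  ind_cols <- setdiff(cols, sd_cols)
  vals <- as.matrix(df[ind_cols])
  rownames(vals) <- df$strain
  sds <- NULL
  if (length(sd_cols)) {
    sds <- matrix(NA_real_, nrow(vals), ncol(vals),
                  dimnames = dimnames(vals))
    for (sc in sd_cols) {
      ind <- sub("_sd$", "", sc)
      if (ind %in% ind_cols) sds[, ind] <- df[[sc]]
    }
  }
  if (length(orientation) > 1 && !is.null(names(orientation)))
    orientation <- orientation[ind_cols]
  IndicatorMatrix(vals, sds = sds, orientation = orientation)
}

#' @rdname readIndicatorMatrix
#' @export
writeIndicatorMatrix <- function(x, path) {
  v <- indicatorValues(x)
  df <- data.frame(strain = rownames(v), v, check.names = FALSE)
  s <- indicatorSds(x)
  if (!is.null(s)) {
    s <- as.data.frame(s)
    names(s) <- paste0(colnames(v), "_sd")
    df <- cbind(df, s)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
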