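#' Default indicator templates for synthetic panels
#'
#' The ten screening indicators with realistic scale ranges for lactic acid
#' bacteria panels: five percent-scale assays (hydroxyl-radical, ABTS+ and
#' DPPH scavenging, superoxide scavenging, ferrous-ion chelation) on
#' 10–99 %, ferric-reducing power on 35–275 umol/L FeSO4 equivalent,
#' exopolysaccharide yield on 330–1100 mg/L, titratable acidity on
#' 31–77 g/L lactic acid equivalent, and two inhibition-zone diameters on
#' 10–30 mm. All are benefit-type indicators.
#'
#' @return data.frame with columns `name`, `lo`, `hi`, `unit`,
#'   `orientation`.
#' @export
defaultIndicatorSpecs <- function() {
  data.frame(
    name = c("OH", "ABTS", "DPPH", "O2", "FICC",
             "FRAP", "EPS", "LacticAcid", "AntiSaureus", "AntiEcoli"),
    lo = c(10, 10, 10, 10, 10, 35, 330, 31, 10, 10),
    hi = c(99, 99, 99, 99, 99, 275, 1100, 77, 30, 30),
    unit = c("%", "%", "%", "%", "%", "umol/L", "mg/L", "g/L", "mm", "mm"),
    orientation = "benefit",
    stringsAsFactors = FALSE)
}

#' Generate a synthetic strain panel with known dominance structure
#'
#' Draws per-strain true indicator means and replicate-level readings that
#' mimic a real screening panel: triplicate measurements with small
#' multiplicative noise around strain-level means on realistic,
#' incommensurate scales. Three dominance profiles control the ground
#' truth:
#' \describe{
#'   \item{`none`}{means drawn independently and uniformly per indicator.}
#'   \item{`total-order`}{strain 1 strictly beats strain 2 beats strain 3 ...
#'     on every benefit indicator; draws are sorted with a minimum gap of 1\%
#'     of the indicator range between consecutive strains.}
#'   \item{`single-dominant`}{strain 1 is drawn in the top 5\% of every
#'     benefit range, all other strains strictly below it.}
#' }
#' Replicates are `mean * (1 + N(0, cv))`, truncated at zero (at the default
#' 2\% coefficient of variation truncation is essentially never active).
#' Cost-type indicators, if present in `indicators`, have the dominance
#' order applied in reverse (the dominant strain gets the lowest value).
#'
#' @param nStrains number of strains (>= 2).
#' @param indicators indicator template data.frame as from
#'   [defaultIndicatorSpecs()] (columns `name`, `lo`, `hi`, `unit`,
#'   `orientation`).
#' @param replicateCV coefficient of variation of replicate noise,
#'   default 0.02.
#' @param nReplicates replicates per strain and indicator, default 3.
#' @param dominance one of `"none"`, `"total-order"`, `"single-dominant"`.
#' @param seed integer seed; identical seeds give bit-identical panels, and
#'   the caller's RNG state is left untouched.
#' @return A list of class `SyntheticPanel`:
#' \describe{
#'   \item{records}{long data.frame `strain`, `indicator`, `replicate`,
#'     `value` consumable by [buildIndicatorMatrix()].}
#'   \item{trueMeans}{strains x indicators matrix of noise-free means.}
#'   \item{dominanceOrder}{strain labels best-to-worst (`NULL` for
#'     `"none"`).}
#'   \item{config}{echo of the generator settings.}
#' }
#' @examples
#' panel <- generatePanel(5, dominance = "total-order", seed = 7)
#' head(panel$records)
#' @export
generatePanel <- function(nStrains, indicators = defaultIndicatorSpecs(),
                          replicateCV = 0.02, nReplicates = 3,
                          dominance = c("none", "total-order", "single-dominant"),
                          seed = 1) {
  dominance <- match.arg(dominance)
  if (nStrains < 2L) .validationError("need at least 2 strains, got %d", nStrains)
  if (replicateCV < 0) .validationError("replicateCV must be non-negative")
  if (nReplicates < 1L) .validationError("need at least 1 replicate")
  if (any(indicators$hi <= indicators$lo))
    .validationError("indicator ranges must be positive (hi > lo)")

  strains <- sprintf("S%02d", seq_len(nStrains))
  p <- nrow(indicators)
  gap <- 0.01 * (indicators$hi - indicators$lo)
  if (dominance == "total-order" &&
      any((nStrains - 1) * gap > (indicators$hi - indicators$lo)))
    .validationError("total-order gaps infeasible for %d strains", nStrains)

  .withSeed(seed, {
    means <- matrix(NA_real_, nStrains, p,
                    dimnames = list(strains, indicators$name))
    for (j in seq_len(p)) {
      lo <- indicators$lo[j]; hi <- indicators$hi[j]; g <- gap[j]
      m <- switch(dominance,
        "none" = runif(nStrains, lo, hi),
        "total-order" = {
          # sorted draws on a shrunk support, then spread by the minimum gap:
          # guarantees strictly decreasing means with gap >= 1% of range
          z <- sort(runif(nStrains, lo, hi - (nStrains - 1) * g))
          rev(z + (seq_len(nStrains) - 1) * g)
        },
        "single-dominant" = {
          cut <- hi - 0.05 * (hi - lo)
          c(runif(1, cut, hi), runif(nStrains - 1, lo, cut - g))
        })
      # mirror within the range for cost indicators so the dominant strain
      # gets the most desirable (lowest) value
      if (indicators$orientation[j] == "cost") m <- lo + hi - m
      means[, j] <- m
    }
    reps <- expand.grid(replicate = seq_len(nReplicates),
                        indicator = indicators$name, strain = strains,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- means[cbind(reps$strain, reps$indicator)]
    noise <- if (replicateCV > 0) rnorm(nrow(reps), 0, replicateCV) else 0
    reps$value <- pmax(0, mu * (1 + noise))
    records <- reps[, c("strain", "indicator", "replicate", "value")]

    structure(list(
      records = records,
      trueMeans = means,
      dominanceOrder = if (dominance == "none") NULL else strains,
      config = list(nStrains = nStrains, replicateCV = replicateCV,
                    nReplicates = nReplicates, dominance = dominance,
                    seed = seed)),
      class = "SyntheticPanel")
  })
}

#' @export
print.SyntheticPanel <- function(x, ...) {
  cat(sprintf("SyntheticPanel: %d strains x %d indicators, %d replicates, CV %.3g, profile '%s', seed %d\n",
              x$config$nStrains, ncol(x$trueMeans), x$config$nReplicates,
              x$config$replicateCV, x$config$dominance, x$config$seed))
  invisible(x)
}

#' Build an IndicatorMatrix from a synthetic panel
#'
#' Convenience wrapper: aggregates the replicate records of a
#' [generatePanel()] result into the decision matrix.
#'
#' @param panel a `SyntheticPanel`.
#' @return An [IndicatorMatrix-class].
#' @export
panelMatrix <- function(panel) {
  stopifnot(inherits(panel, "SyntheticPanel"))
  buildIndicatorMatrix(panel$records,
                       indicators = colnames(panel$trueMeans),
                       strains = rownames(panel$trueMeans))
}

.fixturePath <- function(file) {
  system.file("extdata", file, package = "StrainScreen", mustWork = TRUE)
}

#' Packaged reference antioxidant panel (seven LAB strains, six assays)
#'
#' The published antioxidant screening panel of seven lactic acid bacteria
#' from rubing cheese: per-strain triplicate means and standard deviations
#' for hydroxyl-radical (`OH`), ABTS+ (`ABTS`), DPPH and superoxide (`O2`)
#' scavenging (percent), ferrous-ion chelating capacity (`FICC`, percent)
#' and ferric-reducing power (`FRAP`, umol/L FeSO4 equivalent). Strain
#' labels are kept verbatim from the source table; note the table labels
#' strain W3F *E. durans* although it is elsewhere identified as
#' *E. lactis* — the fixture does not resolve that inconsistency.
#'
#' All six indicators are benefit-oriented. This 7 x 6 matrix is the
#' directly transcribable part of the full 7 x 10 screening matrix (the
#' exopolysaccharide, acidity and antibacterial columns of the original
#' study were published only as figures).
#'
#' @return An [IndicatorMatrix-class], 7 strains x 6 indicators with SDs.
#' @examples
#' m <- table1Fixture()
#' columnSummary(m, "FICC", "max")  # 54.70
#' @export
table1Fixture <- function() {
  m <- readIndicatorMatrix(.fixturePath("table1_antioxidant.csv"),
                           orientation = "benefit")
  rd <- SummarizedExperiment::rowData(m)
  rd$unit <- c("%", "%", "%", "%", "%", "umol/L")
  SummarizedExperiment::rowData(m) <- rd
  m
}

#' Packaged reference entropy-weight table (ten indicators)
#'
#' The published per-indicator entropy `Ej`, information utility `Dj` and
#' weight `Wj` (percent) for the ten screening indicators, as printed
#' (2-decimal `Ej`/`Dj`, 2-decimal percent `Wj`).
#'
#' @return data.frame with columns `indicator`, `Ej`, `Dj`, `Wj_percent`.
#' @export
table2Fixture <- function() {
  read.csv(.fixturePath("table2_entropy_weights.csv"),
           stringsAsFactors = FALSE)
}

#' Packaged reference TOPSIS score table (seven strains)
#'
#' The published per-strain distances to the ideal-best (`d_plus`) and
#' ideal-worst (`d_minus`) solutions, relative closeness `ci` and ranking
#' for the seven-strain screen, as printed.
#'
#' @return data.frame with columns `strain`, `d_plus`, `d_minus`, `ci`,
#'   `rank`.
#' @export
table3Fixture <- function() {
  read.csv(.fixturePath("table3_topsis_scores.csv"),
           stringsAsFactors = FALSE)
}
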