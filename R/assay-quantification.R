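#' Radical scavenging / chelation percentage from an absorbance triplet
#'
#' Converts one reading set of a colorimetric inhibition assay (DPPH, ABTS+,
#' hydroxyl radical, superoxide anion, or ferrous-ion chelation) into the
#' percent activity `[1 - (As - Ab)/Ac] * 100`, where `As` is the sample
#' absorbance, `Ab` the sample blank (reagent replaced by solvent) and `Ac`
#' the control (sample replaced by blank medium).
#'
#' Values are deliberately not clamped to `[0, 100]`: a negative result is a
#' pro-oxidant (or otherwise anomalous) reading and is reported as-is so data
#' problems stay visible.
#'
#' @param sampleAbs,blankAbs,controlAbs absorbance readings (same length,
#'   recycled scalars allowed); all must be finite and non-negative, and
#'   `controlAbs` strictly positive.
#' @param assay optional assay label (`"DPPH"`, `"ABTS"`, `"OH"`, `"O2"`,
#'   `"FICC"`), used only in error messages.
#' @return Numeric vector of percentages.
#' @examples
#' scavengingPercent(0.5, 0.1, 0.8)  # 50 %
#' @export
scavengingPercent <- function(sampleAbs, blankAbs, controlAbs, assay = NULL) {
  n <- max(length(sampleAbs), length(blankAbs), length(controlAbs))
  sampleAbs <- rep_len(as.numeric(sampleAbs), n)
  blankAbs <- rep_len(as.numeric(blankAbs), n)
  controlAbs <- rep_len(as.numeric(controlAbs), n)
  lab <- if (is.null(assay)) "scavenging assay" else paste0(assay, " assay")
  if (any(!is.finite(sampleAbs)) || any(!is.finite(blankAbs)) ||
      any(!is.finite(controlAbs)))
    .validationError("%s: absorbances must be finite", lab)
  if (any(sampleAbs < 0) || any(blankAbs < 0) || any(controlAbs < 0))
    .validationError("%s: absorbances must be non-negative", lab)
  if (any(controlAbs == 0))
    .degenerateError("%s: control absorbance is zero, percent undefined", lab)
  (1 - (sampleAbs - blankAbs) / controlAbs) * 100
}

#' Fit a linear standard curve by ordinary least squares
#'
#' Regresses absorbance on concentration for a calibration series (e.g. a
#' glucose series for the phenol-sulfuric-acid sugar assay, or a FeSO4 series
#' for ferric-reducing power) and reports slope, intercept and the squared
#' Pearson correlation.
#'
#' @param concentration,absorbance numeric vectors of equal length, at least
#'   two points with distinct concentrations.
#' @param unit concentration unit label stored on the curve.
#' @return A [LinearStandardCurve-class].
#' @examples
#' x <- c(0, 25, 50, 100)
#' fitStandardCurve(x, 0.0039 * x + 0.0033, unit = "mg/L")
#' @export
fitStandardCurve <- function(concentration, absorbance, unit = "") {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) != length(absorbance))
    .validationError("calibration vectors must have equal length")
  if (length(concentration) < 2L)
    .validationError("at least two calibration points are required")
  if (length(unique(concentration)) < 2L)
    .degenerateError("all calibration concentrations identical; the curve is degenerate")
  fit <- lm(absorbance ~ concentration)
  slope <- unname(coef(fit)[["concentration"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  if (!is.finite(slope) || slope == 0)
    .degenerateError("fitted slope is zero; absorbance does not respond to concentration")
  r2 <- if (sd(absorbance) == 0) 1 else cor(concentration, absorbance)^2
  linearStandardCurve(slope, intercept, rSquared = r2, unit = unit)
}

#' Invert a standard curve: absorbance to concentration
#'
#' Solves `absorbance = slope * x + intercept` for the concentration `x`.
#' Negative concentrations (absorbance below the intercept) are returned
#' unclamped with a warning so out-of-range readings stay visible.
#'
#' @param curve a [LinearStandardCurve-class].
#' @param absorbance numeric vector of readings.
#' @return Concentrations in `curve@unit`.
#' @examples
#' eps <- epsGlucoseCurve()
#' invertStandardCurve(eps, 0.3933)  # 100 mg/L glucose equivalent
#' @export
invertStandardCurve <- function(curve, absorbance) {
  stopifnot(is(curve, "LinearStandardCurve"))
  validObject(curve)
  absorbance <- as.numeric(absorbance)
  if (any(!is.finite(absorbance)))
    .validationError("absorbance readings must be finite")
  conc <- (absorbance - curve@intercept) / curve@slope
  if (any(conc < 0))
    warning(warningCondition(
      sprintf("%d reading(s) below the curve intercept give negative concentration",
              sum(conc < 0)),
      class = c("strainscreen_negative_concentration", "warning", "condition")))
  conc
}

#' The published exopolysaccharide glucose standard curve
#'
#' The glucose calibration for the phenol-sulfuric-acid assay used to
#' quantify exopolysaccharide, `absorbance = 0.0039 x + 0.0033`
#' (R^2 = 0.9994), with `x` in mg/L glucose equivalent.
#'
#' @return A [LinearStandardCurve-class].
#' @export
epsGlucoseCurve <- function() {
  linearStandardCurve(0.0039, 0.0033, rSquared = 0.9994, unit = "mg/L")
}

#' Synthetic FeSO4 reference curve for ferric-reducing power
#'
#' A plausible synthetic FeSO4 calibration (slope 0.002 AU per umol/L,
#' intercept 0.05 AU) shipped for examples and tests only. Real analyses
#' must supply the calibration measured on their own instrument;
#' FRAP curves are instrument- and batch-specific.
#'
#' @return A [LinearStandardCurve-class].
#' @export
frapSyntheticCurve <- function() {
  linearStandardCurve(0.002, 0.05, rSquared = NA_real_, unit = "umol/L")
}

#' Ferric reducing antioxidant power as FeSO4 equivalent
#'
#' Converts a FRAP assay absorbance (Fe3+-TPTZ reduction, read at 593 nm)
#' into a FeSO4-equivalent concentration in umol/L via a FeSO4 standard
#' curve. Identical arithmetic to [invertStandardCurve()]; the curve's unit
#' must be umol/L.
#'
#' @param absorbance numeric vector of readings.
#' @param curve a FeSO4 [LinearStandardCurve-class].
#' @return FeSO4-equivalent concentrations (umol/L).
#' @examples
#' frapEquivalent(0.596, frapSyntheticCurve())  # 273 umol/L
#' @export
frapEquivalent <- function(absorbance, curve = frapSyntheticCurve()) {
  invertStandardCurve(curve, absorbance)
}

#' Titratable acidity as lactic acid equivalent
#'
#' Standard titrimetric conversion of a NaOH end-point titration into g/L
#' lactic acid equivalent:
#' `acidity = c_NaOH * V_NaOH * M_lactic / V_sample`
#' with the molar mass of lactic acid fixed at 90.08 g/mol. With
#' concentrations in mol/L and volumes in mL this yields g/L directly
#' (mmol NaOH x 90.08 mg/mmol per mL of sample).
#'
#' @param naohVolume titrant volume at the end point (mL), >= 0.
#' @param naohConcentration titrant concentration (mol/L), default 0.1.
#' @param sampleVolume titrated sample volume (mL), > 0.
#' @return Acidity in g/L lactic acid equivalent.
#' @examples
#' titratableAcidity(10, 0.1, 10)  # 9.008 g/L
#' @export
titratableAcidity <- function(naohVolume, naohConcentration = 0.1,
                              sampleVolume = 10) {
  lacticMolarMass <- 90.08
  n <- max(length(naohVolume), length(naohConcentration), length(sampleVolume))
  naohVolume <- rep_len(as.numeric(naohVolume), n)
  naohConcentration <- rep_len(as.numeric(naohConcentration), n)
  sampleVolume <- rep_len(as.numeric(sampleVolume), n)
  if (any(!is.finite(naohVolume)) || any(naohVolume < 0))
    .validationError("NaOH volume must be finite and non-negative")
  if (any(!is.finite(naohConcentration)) || any(naohConcentration <= 0))
    .validationError("NaOH concentration must be positive")
  if (any(!is.finite(sampleVolume)) || any(sampleVolume <= 0))
    .degenerateError("sample volume must be positive; acidity per zero volume is undefined")
  naohConcentration * naohVolume * lacticMolarMass / sampleVolume
}

#' Inhibition-zone diameter, full or net of the well
#'
#' Agar-well diffusion zones are measured as the full clearing diameter
#' including the well (default 9 mm). `net = TRUE` subtracts the well to give
#' the halo width beyond it; zero (no inhibition) stays zero either way.
#'
#' @param zoneDiameter measured zone diameters (mm); each must be 0 (no
#'   inhibition) or at least `wellDiameter`.
#' @param wellDiameter punched-well diameter (mm), default 9.
#' @param net subtract the well diameter?
#' @return Zone diameters (mm), full or net.
#' @export
zoneDiameter <- function(zoneDiameter, wellDiameter = 9, net = FALSE) {
  zoneDiameter <- as.numeric(zoneDiameter)
  if (any(!is.finite(zoneDiameter)) || any(zoneDiameter < 0))
    .validationError("zone diameters must be finite and non-negative")
  bad <- zoneDiameter > 0 & zoneDiameter < wellDiameter
  if (any(bad))
    .validationError("zone diameter(s) %s are positive but smaller than the %g mm well",
                     paste(zoneDiameter[bad], collapse = ", "), wellDiameter)
  if (net) ifelse(zoneDiameter == 0, 0, zoneDiameter - wellDiameter)
  else zoneDiameter
}

#' Reduce long-format absorbance records to per-strain indicator statistics
#'
#' Takes replicate-level readings of the inhibition-percentage assays in long
#' format — columns `strain`, `assay`, `replicate`, `role`
#' (`sample`/`blank`/`control`) and `value` — computes the percent activity
#' of every replicate with [scavengingPercent()], and reduces replicates by
#' arithmetic mean with the standard deviation alongside. Percentages, not
#' raw absorbances, are averaged.
#'
#' @param records data.frame (e.g. from [utils::read.csv()] on the long CSV
#'   interchange format) with the five columns above.
#' @return data.frame with columns `strain`, `indicator`, `mean`, `sd`, `n`,
#'   one row per (strain, assay).
#' @export
quantifyAssays <- function(records) {
  needed <- c("strain", "assay", "replicate", "role", "value")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    .validationError("records lack column(s): %s", paste(missing, collapse = ", "))
  if (!all(records$role %in% c("sample", "blank", "control")))
    .validationError("role must be one of sample/blank/control")
  key <- interaction(records$strain, records$assay, records$replicate, drop = TRUE)
  per_rep <- lapply(split(records, key), function(grp) {
    get1 <- function(role) {
      v <- grp$value[grp$role == role]
      if (length(v) != 1L)
        .validationError("strain %s, assay %s, replicate %s: expected exactly one '%s' reading, found %d",
                         grp$strain[1], grp$assay[1], grp$replicate[1], role, length(v))
      v
    }
    data.frame(strain = grp$strain[1], indicator = grp$assay[1],
               percent = scavengingPercent(get1("sample"), get1("blank"),
                                           get1("control"), assay = grp$assay[1]))
  })
  per_rep <- do.call(rbind, per_rep)
  out_key <- interaction(per_rep$strain, per_rep$indicator, drop = TRUE)
  out <- lapply(split(per_rep, out_key), function(grp) {
    data.frame(strain = grp$strain[1], indicator = grp$indicator[1],
               mean = mean(grp$percent),
               sd = if (nrow(grp) > 1) sd(grp$percent) else NA_real_,
               n = nrow(grp))
  })
  out <- do.call(rbind, out)
  # preserve first-appearance order of the input
  ord <- order(match(out$strain, unique(records$strain)),
               match(out$indicator, unique(records$assay)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
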