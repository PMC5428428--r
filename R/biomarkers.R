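#' Glucose-homeostasis indices and classifications
#'
#' Closed-form homeostasis-model indices from fasting glucose and insulin,
#' the pre-diabetes classification used throughout the package, and a
#' pluggable percent-body-fat equation.
#'
#' @name biomarkers
NULL

#' HOMA insulin-resistance and beta-cell indices
#'
#' The default `homa1` variant is the closed-form model:
#' IR = FPG x insulin / 22.5 and beta = 20 x insulin / (FPG - 3.5).
#' The iterative HOMA2 computer model has no closed form; the
#' `homa2_approx` variant multiplies the closed-form values by user-supplied
#' recalibration constants (both 1 by default), making the mapping explicit
#' and pluggable rather than pretending to reproduce the iterative model.
#' Beta is undefined (returned as `NA` with a warning) when FPG <= 3.5 mmol/L.
#'
#' @param fpg Fasting plasma glucose, mmol/L (> 0).
#' @param insulin Fasting insulin, uIU/mL (> 0).
#' @param variant `"homa1"` or `"homa2_approx"`.
#' @param recalibration Named numeric `c(ir = ..., beta = ...)` multipliers
#'   applied under `homa2_approx`.
#' @return A list with vectors `homa_ir` and `homa_beta_pct`.
#' @export
homa_indices <- function(fpg, insulin, variant = c("homa1", "homa2_approx"),
                         recalibration = c(ir = 1, beta = 1)) {
  variant <- match.arg(variant)
  if (any(fpg <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE)) {
    abort("fpg and insulin must be positive")
  }
  ir <- fpg * insulin / 22.5
  beta <- rep(NA_real_, length(fpg))
  ok <- !is.na(fpg) & fpg > 3.5
  beta[ok] <- 20 * insulin[ok] / (fpg[ok] - 3.5)
  if (any(!ok & !is.na(fpg))) {
    warn("HOMA-beta undefined for FPG <= 3.5 mmol/L; returned as NA")
  }
  if (variant == "homa2_approx") {
    ir <- ir * recalibration[["ir"]]
    beta <- beta * recalibration[["beta"]]
  }
  list(homa_ir = ir, homa_beta_pct = beta)
}

#' Pre-diabetes classification
#'
#' Pre-diabetes is fasting plasma glucose in [5.5, 7.0) mmol/L or HbA1c in
#' [5.7, 6.4] percent. The FPG upper bound is exclusive (7.0 mmol/L is the
#' diabetes threshold); the HbA1c bounds are inclusive. Missing inputs give a
#' missing classification.
#'
#' @param fpg Fasting plasma glucose, mmol/L.
#' @param hba1c Glycated haemoglobin, percent.
#' @return Logical vector.
#' @export
classify_prediabetes <- function(fpg, hba1c) {
  (fpg >= 5.5 & fpg < 7.0) | (hba1c >= 5.7 & hba1c <= 6.4)
}

#' Percent body fat from BMI and waist circumference
#'
#' Linear form `a + b * bmi + c * wc + d * female`, clipped to [3, 60]
#' percent. The published anthropometric equations for Chinese adults are not
#' reproduced here; the default coefficients are a synthetic surrogate chosen
#' to give population medians in the low-to-mid twenties and are clearly
#' non-canonical. Supply your own coefficients for substantive use.
#'
#' @param bmi Body-mass index, kg/m^2.
#' @param wc_cm Waist circumference, cm.
#' @param female Indicator (1/TRUE = female).
#' @param coefficients Numeric `c(a, b, c, d)`.
#' @return Percent body fat, clipped to [3, 60].
#' @export
body_fat_pct <- function(bmi, wc_cm, female,
                         coefficients = c(-27.5, 1.15, 0.25, 7.5)) {
  a <- coefficients[1]; b <- coefficients[2]
  c_ <- coefficients[3]; d <- coefficients[4]
  bf <- a + b * bmi + c_ * wc_cm + d * as.numeric(female)
  pmin(pmax(bf, 3), 60)
}

#' Derive biomarker columns on a participant table
#'
#' Appends (never overwrites) `homa_ir`, `homa_beta_pct`, `prediabetes`,
#' `bmi` and `bf_pct` where the inputs are available.
#'
#' @param participants Participant tibble with `fpg_mmol_l`, `insulin_uiu_ml`,
#'   `hba1c_pct` and anthropometry columns.
#' @param variant HOMA variant, see [homa_indices()].
#' @return The tibble with derived columns appended.
#' @export
derive_biomarkers <- function(participants, variant = "homa1") {
  p <- participants
  if (!"bmi" %in% names(p) && all(c("weight_kg", "height_m") %in% names(p))) {
    p$bmi <- p$weight_kg / p$height_m^2
  }
  if (!"bf_pct" %in% names(p) && all(c("bmi", "wc_cm") %in% names(p))) {
    p$bf_pct <- body_fat_pct(p$bmi, p$wc_cm, p$female)
  }
  if (!"overweight" %in% names(p) && "bmi" %in% names(p)) {
    p$overweight <- p$bmi >= 25
  }
  homa <- homa_indices(p$fpg_mmol_l, p$insulin_uiu_ml, variant = variant)
  if (!"homa_ir" %in% names(p)) p$homa_ir <- homa$homa_ir
  if (!"homa_beta_pct" %in% names(p)) p$homa_beta_pct <- homa$homa_beta_pct
  if (!"prediabetes" %in% names(p)) {
    p$prediabetes <- classify_prediabetes(p$fpg_mmol_l, p$hba1c_pct)
  }
  p
}
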