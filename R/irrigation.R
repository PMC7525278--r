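#' Sodium adsorption ratio
#'
#' `sar = Na / sqrt(Ca + Mg)` in the `"paper"` convention, or the USDA form
#' `Na / sqrt((Ca + Mg)/2)` in the `"standard"` convention. All inputs in
#' meq/L. A zero alkaline-earth sum yields `NA` (undefined), not an error.
#'
#' @param na,ca,mg Cation concentrations in meq/L.
#' @param convention `"paper"` (no halving, the definition used by the
#'   source compilation) or `"standard"` (USDA).
#' @return Dimensionless index value(s).
#' @export
#' @examples
#' sar(4, 2, 2)                         # 2
#' sar(4, 2, 2, convention = "standard") # 2.828
sar <- function(na, ca, mg, convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  denom <- ca + mg
  if (convention == "standard") denom <- denom / 2
  out <- ifelse(ca + mg > 0, na / sqrt(denom), NA_real_)
  unname(out)
}

#' Soluble sodium percentage
#'
#' `(Na + K) * 100 / (Ca + Mg + Na + K)`, inputs in meq/L. All-zero cations
#' yield `NA`.
#'
#' @param na,k,ca,mg Cation concentrations in meq/L.
#' @return Percentage in \[0, 100\].
#' @export
na_percent <- function(na, k, ca, mg) {
  tot <- na + k + ca + mg
  unname(ifelse(tot > 0, (na + k) * 100 / tot, NA_real_))
}

#' Residual sodium carbonate
#'
#' `(HCO3 + CO3) - (Ca + Mg)` in meq/L; may be negative.
#'
#' @param hco3,co3,ca,mg Concentrations in meq/L.
#' @return meq/L.
#' @export
rsc <- function(hco3, co3 = 0, ca = 0, mg = 0) {
  (hco3 + co3) - (ca + mg)
}

#' Magnesium adsorption ratio
#'
#' `Mg * 100 / (Ca + Mg)`, inputs in meq/L.
#'
#' @param ca,mg Concentrations in meq/L.
#' @return Percentage in \[0, 100\]; `NA` when `ca + mg == 0`.
#' @export
mar <- function(ca, mg) {
  unname(ifelse(ca + mg > 0, mg * 100 / (ca + mg), NA_real_))
}

#' Kelly ratio
#'
#' `Na / (Ca + Mg)`, inputs in meq/L.
#'
#' @param na,ca,mg Concentrations in meq/L.
#' @return Dimensionless; `NA` when `ca + mg == 0`.
#' @export
kelly_ratio <- function(na, ca, mg) {
  unname(ifelse(ca + mg > 0, na / (ca + mg), NA_real_))
}

#' Salinity hazard class from electrical conductivity
#'
#' C1 (low) below 250 uS/cm, C2 (medium) in \[250, 750), C3 (high) in
#' \[750, 2250), C4 (very high) at 2250 uS/cm and above. Interval bounds are
#' lower-inclusive.
#'
#' @param ec Electrical conductivity in uS/cm (nonnegative).
#' @return Factor with levels C1--C4.
#' @export
classify_salinity <- function(ec) {
  stopifnot(all(ec >= 0, na.rm = TRUE))
  cut(ec, breaks = c(-Inf, 250, 750, 2250, Inf),
      labels = c("C1", "C2", "C3", "C4"), right = FALSE)
}

#' Alkalinity (sodium) hazard class from SAR
#'
#' S1 (low) below 10, S2 (medium) in \[10, 18), S3 (high) in \[18, 26), S4
#' (very high) at 26 and above; lower-inclusive bounds.
#'
#' @param sar Sodium adsorption ratio (nonnegative).
#' @return Factor with levels S1--S4.
#' @export
classify_sodium <- function(sar) {
  stopifnot(all(sar >= 0, na.rm = TRUE))
  cut(sar, breaks = c(-Inf, 10, 18, 26, Inf),
      labels = c("S1", "S2", "S3", "S4"), right = FALSE)
}

#' Irrigation suitability verdict for an index value
#'
#' Published cut-offs: Na% below 30 suitable, above 60 unsuitable, marginal
#' between; RSC below 1.25 / above 2.5; MAR at most 50 suitable, above 50
#' unsuitable; Kelly ratio below 1 suitable, above 3 unsuitable. The open
#' interval (1, 3) for the Kelly ratio is labelled marginal: the published
#' rule defines only the two extremes and leaves the gap unnamed.
#'
#' @param index_name One of `"na_percent"`, `"rsc"`, `"mar"`, `"kr"`.
#' @param value Index value(s).
#' @return Character vector of verdicts (`"suitable"`, `"marginal"`,
#'   `"unsuitable"`; `NA` propagates).
#' @export
classify_suitability <- function(index_name, value) {
  thresholds <- list(
    na_percent = c(lo = 30, hi = 60),
    rsc        = c(lo = 1.25, hi = 2.5),
    mar        = c(lo = 50, hi = 50),
    kr         = c(lo = 1, hi = 3)
  )
  th <- thresholds[[index_name]]
  if (is.null(th)) stop("unknown index: ", index_name, call. = FALSE)
  if (index_name == "mar") {
    return(ifelse(is.na(value), NA_character_,
                  ifelse(value > 50, "unsuitable", "suitable")))
  }
  ifelse(is.na(value), NA_character_,
         ifelse(value < th["lo"], "suitable",
                ifelse(value > th["hi"], "unsuitable", "marginal")))
}

#' Irrigation suitability assessment for a sample table
#'
#' Converts the major cations and anions to meq/L, computes SAR, Na%, RSC,
#' MAR and the Kelly ratio per sample, and attaches the salinity (C1--C4)
#' and alkalinity (S1--S4) hazard classes plus per-index suitability
#' verdicts.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param sar_convention Passed to [sar()]; default `"paper"`.
#' @param constants Ion constants table for the meq conversion.
#' @return Data frame, one row per sample.
#' @export
irrigation_assess <- function(ds, sar_convention = c("paper", "standard"),
                              constants = ion_constants()) {
  ds <- as_water_dataset(ds)
  sar_convention <- match.arg(sar_convention)
  s <- ds$samples
  meq <- function(p) to_meq(s[[p]], p, constants)
  na <- meq("na"); k <- meq("k"); ca <- meq("ca"); mg <- meq("mg")
  hco3 <- meq("hco3"); co3 <- to_meq(s$co3, "co3", constants)
  out <- data.frame(
    sample_id = s$sample_id,
    sar = sar(na, ca, mg, convention = sar_convention),
    na_percent = na_percent(na, k, ca, mg),
    rsc = rsc(hco3, co3, ca, mg),
    mar = mar(ca, mg),
    kr = kelly_ratio(na, ca, mg),
    stringsAsFactors = FALSE
  )
  out$salinity_class <- as.character(classify_salinity(s$ec))
  out$sodium_class <- as.character(classify_sodium(out$sar))
  out$na_percent_verdict <- classify_suitability("na_percent", out$na_percent)
  out$rsc_verdict <- classify_suitability("rsc", out$rsc)
  out$mar_verdict <- classify_suitability("mar", out$mar)
  out$kr_verdict <- classify_suitability("kr", out$kr)
  out
}

#' Hazard-class frequency summary
#'
#' Counts and percentages of samples per salinity and alkalinity hazard
#' class, shaped like the conventional C/S classification grid.
#'
#' @param irrigation Output of [irrigation_assess()].
#' @return Data frame with columns `hazard`, `class`, `n`, `percent`.
#' @export
irrigation_summary <- function(irrigation) {
  n <- nrow(irrigation)
  tab <- function(x, levels, hazard) {
    counts <- table(factor(x, levels = levels))
    data.frame(hazard = hazard, class = levels, n = as.integer(counts),
               percent = 100 * as.integer(counts) / n,
               stringsAsFactors = FALSE)
  }
  rbind(
    tab(irrigation$salinity_class, c("C1", "C2", "C3", "C4"), "salinity"),
    tab(irrigation$sodium_class, c("S1", "S2", "S3", "S4"), "alkalinity")
  )
}
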