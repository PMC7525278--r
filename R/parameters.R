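#' Reference table of monitored parameters
#'
#' Master table of the fifteen monitored parameters: measurement unit, WHO
#' drinking-water guideline value `si` (for pH the guideline is the range
#' `si_lower`--`si`, i.e. 6.5--8.5; all other guidelines are upper bounds),
#' the assigned WQI weight `weight_wi` (integers 1--5), the relative weight
#' column as printed in the source compilation (`printed_wi`; kept for
#' comparison runs only -- it does not sum to 1), and the published
#' descriptive summary (`min`, `max`, `mean`, `sd`) that drives the
#' synthetic-data generator.
#'
#' Concentrations of major ions are in mg/L, trace metals in ug/L, EC in
#' uS/cm; pH is dimensionless.
#'
#' @return A data frame with one row per parameter.
#' @export
#' @examples
#' who_parameter_table()
who_parameter_table <- function() {
  df <- data.frame(
    parameter = c("ph", "ec", "tds", "cl", "so4", "hco3", "na", "k",
                  "ca", "mg", "zn", "co", "cu", "ni", "pb"),
    unit = c("", "uS/cm", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L", "mg/L",
             "mg/L", "mg/L", "ug/L", "ug/L", "ug/L", "ug/L", "ug/L"),
    si_lower = c(6.5, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    si = c(8.5, 1500, 1000, 200, 500, 500, 200, 12, 75, 50,
           3000, 50, 50, 20, 10),
    weight_wi = c(4L, 4L, 4L, 4L, 3L, 1L, 3L, 2L, 2L, 2L, 3L, 1L, 2L, 4L, 5L),
    printed_wi = c(0.05, 0.05, 0.05, 0.10, 0.07, 0.02, 0.04, 0.02, 0.02,
                   0.02, 0.04, 0.01, 0.03, 0.05, 0.06),
    min = c(7.00, 103, 65.9, 35, 76.0, 11.6, 17.2, 2.10, 27.2, 21.2,
            9.00, 8.00, 12.0, 1.00, 2.00),
    max = c(8.21, 1260, 806.0, 115, 168, 430, 39.63, 16.31, 125.2, 41.10,
            74.00, 48.00, 57.00, 71.00, 18.00),
    mean = c(7.23, 426, 228, 93.01, 113, 101, 24.3, 7.03, 101, 26.7,
             26.3, 22.6, 32.6, 27.8, 9.3),
    sd = c(0.38, 289.25, 189.03, 14.11, 19.0, 23.0, 6.30, 3.87, 19.44,
           4.77, 14.45, 10.48, 12.72, 21.01, 3.43),
    stringsAsFactors = FALSE
  )
  df
}

#' Ionic valence and molar mass constants
#'
#' Standard atomic/formula weights and valences for the major ions, used to
#' convert mg/L to meq/L. Editable: pass a modified copy to [to_meq()].
#'
#' @return Data frame with columns `parameter`, `valence`, `molar_mass`
#'   (g/mol).
#' @export
ion_constants <- function() {
  data.frame(
    parameter  = c("na", "k", "ca", "mg", "cl", "so4", "hco3", "co3"),
    valence    = c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L),
    molar_mass = c(22.99, 39.10, 40.08, 24.31, 35.45, 96.06, 61.02, 60.01),
    stringsAsFactors = FALSE
  )
}

#' Receptor exposure profiles for the USEPA dose model
#'
#' Default ingestion/dermal exposure parameters for the two receptor groups:
#' ingestion rate `ir` (L/day), exposed skin surface area `sa` (cm2),
#' exposure frequency `ef` (days/year), exposure time `et` (h/day), exposure
#' duration `ed` (years), body weight `bw` (kg) and averaging time `at`
#' (days, noncarcinogenic).
#'
#' @param receptor `"adult"` or `"child"`.
#' @return A list of class `exposure_profile`.
#' @export
#' @examples
#' exposure_profile("child")
exposure_profile <- function(receptor = c("adult", "child")) {
  receptor <- match.arg(receptor)
  p <- switch(receptor,
    adult = list(ir = 2.0,  sa = 1800, ef = 350, et = 0.58, ed = 70,
                 bw = 65, at = 25550),
    child = list(ir = 0.64, sa = 6660, ef = 350, et = 1.0,  ed = 6,
                 bw = 20, at = 2190)
  )
  p$receptor <- receptor
  stopifnot(all(vapply(p[setdiff(names(p), "receptor")], function(x) x > 0,
                       logical(1))))
  structure(p, class = "exposure_profile")
}

#' Reference doses and dermal permeability for the assessed metals
#'
#' Per-metal ingestion and dermal reference doses (ug/kg/day), dermal
#' permeability coefficient `kp` (cm/h) and the gastrointestinal absorption
#' fraction `absg`. The dermal RfD column is canonical; `absg` is retained
#' as metadata only (the stated fractions are not consistent with the
#' printed RfD ratios).
#'
#' @return Data frame keyed by `metal`.
#' @export
rfd_defaults <- function() {
  data.frame(
    metal         = c("zn", "co", "cu", "ni", "pb"),
    rfd_ingestion = c(300, 5, 40, 20, 1.4),
    rfd_dermal    = c(60, 0.06, 12, 5.4, 0.42),
    kp            = c(0.0006, 0.004, 0.001, 0.004, 0.0001),
    absg          = c(0.20, NA, 0.57, 0.04, 0.117),
    stringsAsFactors = FALSE
  )
}

#' Default inter-parameter correlation target for the synthetic generator
#'
#' A transcription of the published Pearson matrix over the twelve variables
#' pH, EC, TDS, Na, K, Ca, Mg, Zn, Co, Cu, Ni, Pb. The printed symmetric
#' halves disagree in sign for a few pairs (Na--Pb, Ca--Pb, pH--Mg); the
#' lower triangle is used, with pH--Mg taken positive as the accompanying
#' text describes that pair as significantly positively correlated. The
#' matrix is approximate and editable; [generate_samples()] applies a
#' nearest positive-semidefinite repair before use.
#'
#' @return A 12 x 12 symmetric correlation matrix with unit diagonal.
#' @export
default_target_correlation <- function() {
  v <- c("ph", "ec", "tds", "na", "k", "ca", "mg", "zn", "co", "cu", "ni", "pb")
  r <- diag(12)
  dimnames(r) <- list(v, v)
  lower <- list(
    ec   = c(ph = -0.24),
    tds  = c(ph = -0.06, ec = 0.50),
    na   = c(ph = -0.13, ec = 0.31, tds = -0.03),
    k    = c(ph = -0.34, ec = 0.14, tds = 0.11, na = 0.24),
    ca   = c(ph = 0.12, ec = 0.10, tds = -0.20, na = 0.21, k = 0.06),
    mg   = c(ph = 0.41, ec = 0.03, tds = -0.05, na = 0.49, k = 0.45,
             ca = 0.22),
    zn   = c(ph = -0.29, ec = 0.10, tds = -0.16, na = 0.27, k = -0.03,
             ca = 0.25, mg = 0.23),
    co   = c(ph = -0.16, ec = -0.06, tds = -0.20, na = -0.03, k = 0.29,
             ca = 0.06, mg = 0.22, zn = 0.11),
    cu   = c(ph = 0.10, ec = -0.18, tds = -0.25, na = 0.09, k = 0.04,
             ca = -0.10, mg = -0.04, zn = 0.16, co = 0.09),
    ni   = c(ph = 0.10, ec = -0.02, tds = -0.02, na = 0.31, k = -0.12,
             ca = -0.01, mg = -0.03, zn = 0.40, co = 0.21, cu = 0.25),
    pb   = c(ph = -0.13, ec = -0.16, tds = -0.08, na = 0.47, k = -0.32,
             ca = 0.41, mg = -0.29, zn = -0.05, co = -0.12, cu = 0.03,
             ni = 0.15)
  )
  for (i in names(lower)) {
    for (j in names(lower[[i]])) {
      r[i, j] <- r[j, i] <- lower[[i]][[j]]
    }
  }
  r
}
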