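#' Average daily dose by ingestion
#'
#' `ADD_ingestion = Cw * IR * EF * ED / (BW * AT)` with `Cw` in ug/L, giving
#' ug/kg/day.
#'
#' @param cw Water concentration(s), ug/L (nonnegative).
#' @param profile An [exposure_profile()].
#' @return Dose(s) in ug/kg/day.
#' @export
#' @examples
#' add_ingestion(26.3, exposure_profile("adult"))
add_ingestion <- function(cw, profile = exposure_profile("adult")) {
  stopifnot(all(cw >= 0, na.rm = TRUE))
  cw * profile$ir * profile$ef * profile$ed / (profile$bw * profile$at)
}

#' Average daily dose by dermal contact
#'
#' `ADD_dermal = Cw * SA * Kp * EF * ET * ED / (BW * AT)`. In the default
#' `"paper"` mode no volumetric conversion is applied, which is the form
#' under which the published adult hazard quotients reproduce; the
#' `"physical"` mode multiplies by CF = 0.001 L/cm3 so the units close
#' dimensionally, giving doses exactly 1000-fold smaller.
#'
#' @param cw Water concentration(s), ug/L (nonnegative).
#' @param profile An [exposure_profile()].
#' @param kp Dermal permeability coefficient, cm/h (positive).
#' @param units `"paper"` (default) or `"physical"`.
#' @return Dose(s) in ug/kg/day.
#' @export
add_dermal <- function(cw, profile = exposure_profile("adult"), kp,
                       units = c("paper", "physical")) {
  stopifnot(all(cw >= 0, na.rm = TRUE), all(kp > 0))
  units <- match.arg(units)
  cf <- if (units == "physical") 0.001 else 1
  cw * profile$sa * kp * profile$ef * profile$et * profile$ed * cf /
    (profile$bw * profile$at)
}

#' Hazard quotient
#'
#' `HQ = ADD / RfD`; a quotient strictly greater than 1 flags potential
#' noncarcinogenic risk.
#'
#' @param add Average daily dose(s), ug/kg/day.
#' @param rfd Reference dose, ug/kg/day (positive).
#' @return Dimensionless quotient(s).
#' @export
hazard_quotient <- function(add, rfd) {
  if (any(rfd <= 0)) stop("reference dose must be positive", call. = FALSE)
  add / rfd
}

#' Hazard index
#'
#' Exact sum of route-specific hazard quotients; strictly greater than 1
#' flags potential cumulative noncarcinogenic risk.
#'
#' @param hqs Numeric vector of hazard quotients (nonempty).
#' @return Dimensionless sum.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) stop("no hazard quotients supplied", call. = FALSE)
  sum(hqs)
}

#' Noncarcinogenic risk report
#'
#' For each assessed metal and receptor, computes the ingestion and dermal
#' average daily doses, the route hazard quotients and the hazard index
#' `HI = HQ_ingestion + HQ_dermal` (exact sum), with flags for quotients
#' strictly above 1. `statistic = "mean"` evaluates the dataset's arithmetic
#' mean concentration per metal (the deterministic summary-level
#' assessment); `"per_sample"` emits one row per sample x metal x receptor.
#'
#' Metals present in the data but missing from the RfD table are skipped
#' with a warning.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param receptors Character vector from `c("adult", "child")`.
#' @param rfd RfD/Kp table, default [rfd_defaults()].
#' @param statistic `"mean"` (default) or `"per_sample"`.
#' @param units Dermal dose convention, see [add_dermal()].
#' @param metals Metals to assess; default all with an RfD entry.
#' @return Data frame of class `risk_report`.
#' @export
risk_report <- function(ds, receptors = c("adult", "child"),
                        rfd = rfd_defaults(),
                        statistic = c("mean", "per_sample"),
                        units = c("paper", "physical"),
                        metals = rfd$metal) {
  ds <- as_water_dataset(ds)
  statistic <- match.arg(statistic)
  units <- match.arg(units)
  receptors <- match.arg(receptors, several.ok = TRUE)
  measured <- intersect(metals, names(ds$samples))
  no_rfd <- setdiff(measured, rfd$metal)
  if (length(no_rfd) > 0) {
    warning("no reference dose for metal(s): ",
            paste(no_rfd, collapse = ", "), "; skipped", call. = FALSE)
    measured <- setdiff(measured, no_rfd)
  }
  if (length(measured) == 0 || nrow(ds$samples) == 0) {
    warning("no assessable metals or samples; empty report", call. = FALSE)
    return(structure(data.frame(), class = c("risk_report", "data.frame")))
  }
  grid <- if (statistic == "mean") {
    expand.grid(metal = measured, receptor = receptors,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(sample_id = ds$samples$sample_id, metal = measured,
                receptor = receptors, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- grid$metal[i]
    prof <- exposure_profile(grid$receptor[i])
    tab <- rfd[rfd$metal == m, ]
    cw <- if (statistic == "mean") {
      mean(ds$samples[[m]], na.rm = TRUE)
    } else {
      ds$samples[[m]][ds$samples$sample_id == grid$sample_id[i]]
    }
    ing <- add_ingestion(cw, prof)
    der <- add_dermal(cw, prof, kp = tab$kp, units = units)
    hq_i <- hazard_quotient(ing, tab$rfd_ingestion)
    hq_d <- hazard_quotient(der, tab$rfd_dermal)
    out <- data.frame(metal = m, receptor = grid$receptor[i], cw = cw,
                      add_ingestion = ing, add_dermal = der,
                      hq_ingestion = hq_i, hq_dermal = hq_d,
                      hi = hq_i + hq_d, stringsAsFactors = FALSE)
    if (statistic == "per_sample") {
      out <- cbind(sample_id = grid$sample_id[i], out,
                   stringsAsFactors = FALSE)
    }
    out
  })
  out <- do.call(rbind, rows)
  out$flag_hq <- out$hq_ingestion > 1 | out$hq_dermal > 1
  out$flag_hi <- out$hi > 1
  structure(out, class = c("risk_report", "data.frame"))
}
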