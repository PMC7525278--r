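#' Gibbs mechanism ratios
#'
#' The Gibbs construction plots total dissolved solids against the cation
#' ratio `Na/(Na + Ca)` and the anion ratio `Cl/(Cl + HCO3)` to separate
#' precipitation-, rock- and evaporation-dominated waters. Ratios are
#' mass-based (mg/L) by default, matching the usual axis labelling;
#' `basis = "meq"` converts to equivalents first.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param basis `"mass"` (default) or `"meq"`.
#' @return Data frame with `sample_id`, `cation_ratio`, `anion_ratio`,
#'   `tds`. Zero denominators yield `NA`.
#' @export
gibbs_ratios <- function(ds, basis = c("mass", "meq")) {
  ds <- as_water_dataset(ds)
  basis <- match.arg(basis)
  s <- ds$samples
  if (basis == "meq") {
    na <- to_meq(s$na, "na"); ca <- to_meq(s$ca, "ca")
    cl <- to_meq(s$cl, "cl"); hco3 <- to_meq(s$hco3, "hco3")
  } else {
    na <- s$na; ca <- s$ca; cl <- s$cl; hco3 <- s$hco3
  }
  data.frame(
    sample_id = s$sample_id,
    cation_ratio = ifelse(na + ca > 0, na / (na + ca), NA_real_),
    anion_ratio = ifelse(cl + hco3 > 0, cl / (cl + hco3), NA_real_),
    tds = s$tds,
    stringsAsFactors = FALSE
  )
}

#' Default Gibbs zone polygons
#'
#' The zone boundaries of the Gibbs diagram are cartographic, not analytic:
#' published versions draw a freehand "boomerang" by eye. This editable set
#' of three polygons (vertices in ratio vs log10 TDS space) approximates the
#' canonical shapes: a rock-dominance body at intermediate TDS and low-to-
#' moderate ratio, an evaporation arm climbing to high TDS at high ratio,
#' and a precipitation corner at low TDS and high ratio. Classification
#' against them is heuristic by construction.
#'
#' @return Named list of data frames with columns `ratio`, `log10_tds`.
#' @export
default_gibbs_polygons <- function() {
  list(
    rock = data.frame(
      ratio = c(0.00, 0.45, 0.70, 0.45, 0.00),
      log10_tds = c(1.80, 1.95, 2.30, 3.00, 3.10)
    ),
    evaporation = data.frame(
      ratio = c(0.45, 1.00, 1.00),
      log10_tds = c(3.00, 2.60, 5.00)
    ),
    precipitation = data.frame(
      ratio = c(0.40, 1.00, 1.00),
      log10_tds = c(0.30, 0.30, 1.90)
    )
  )
}

# Even-odd ray casting; boundary points count as inside.
point_in_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  j <- n
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    # on-edge test
    d <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_edge <- abs(d) < 1e-12 &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !on_edge)
    inside <- inside | on_edge
    j <- i
  }
  inside
}

#' Heuristic Gibbs zone assignment
#'
#' Tests each (ratio, TDS) point against the zone polygons in the order
#' rock, evaporation, precipitation; points outside every polygon are
#' `"indeterminate"`.
#'
#' @param ratio Ion ratio(s) in \[0, 1\].
#' @param tds Total dissolved solids in mg/L (positive).
#' @param polygons Zone polygons, default [default_gibbs_polygons()].
#' @return Character vector of zones.
#' @export
#' @examples
#' classify_gibbs(0.2, 228)    # "rock"
#' classify_gibbs(0.99, 50000) # "evaporation"
classify_gibbs <- function(ratio, tds, polygons = default_gibbs_polygons()) {
  stopifnot(all(ratio >= 0 & ratio <= 1, na.rm = TRUE),
            all(tds > 0, na.rm = TRUE))
  y <- log10(tds)
  zone <- rep("indeterminate", length(ratio))
  for (nm in names(polygons)) {
    p <- polygons[[nm]]
    hit <- zone == "indeterminate" &
      point_in_polygon(ratio, y, p$ratio, p$log10_tds)
    zone[hit] <- nm
  }
  zone[is.na(ratio) | is.na(tds)] <- NA_character_
  zone
}

#' Chadha four-field hydrochemical classification
#'
#' Coordinates are meq percentage differences: `x` is the (Ca+Mg) share of
#' total cations minus the (Na+K) share; `y` is the HCO3 share of total
#' anions (HCO3 + Cl + SO4) minus the (Cl+SO4) share. The sign quadrant
#' determines the facies: field 1 (`x>0, y>0`) Ca-HCO3 recharge waters,
#' field 2 (`x>0, y<0`) Ca-Mg-Cl reverse ion exchange, field 3 (`x<0, y<0`)
#' Na-Cl evaporation-dominated, field 4 (`x<0, y>0`) Na-HCO3 base ion
#' exchange. Points on an axis are assigned to the higher-numbered adjacent
#' field (a deterministic, documented tie rule) and flagged as boundary.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param constants Ion constants for the meq conversion.
#' @return Data frame with `sample_id`, `chadha_x`, `chadha_y`,
#'   `chadha_field` (1--4), `boundary`. Samples with zero total cation or
#'   anion equivalents get `NA` coordinates and field.
#' @export
chadha_classify <- function(ds, constants = ion_constants()) {
  ds <- as_water_dataset(ds)
  s <- ds$samples
  meq <- function(p, v) to_meq(v, p, constants)
  cat_tot <- meq("ca", s$ca) + meq("mg", s$mg) + meq("na", s$na) +
    meq("k", s$k)
  an_tot <- meq("hco3", s$hco3) + meq("cl", s$cl) + meq("so4", s$so4)
  x <- ifelse(cat_tot > 0,
              100 * ((meq("ca", s$ca) + meq("mg", s$mg)) -
                     (meq("na", s$na) + meq("k", s$k))) / cat_tot, NA_real_)
  y <- ifelse(an_tot > 0,
              100 * (meq("hco3", s$hco3) -
                     (meq("cl", s$cl) + meq("so4", s$so4))) / an_tot,
              NA_real_)
  field <- ifelse(x > 0 & y > 0, 1L,
           ifelse(x > 0 & y < 0, 2L,
           ifelse(x < 0 & y < 0, 3L,
           ifelse(x < 0 & y > 0, 4L, NA_integer_))))
  boundary <- !is.na(x) & !is.na(y) & (x == 0 | y == 0)
  # axis ties -> higher-numbered adjacent field
  field[boundary & x == 0 & y > 0] <- 4L   # between 1 and 4
  field[boundary & x == 0 & y < 0] <- 3L   # between 2 and 3
  field[boundary & y == 0 & x > 0] <- 2L   # between 1 and 2
  field[boundary & y == 0 & x < 0] <- 4L   # between 3 and 4
  field[boundary & x == 0 & y == 0] <- 4L  # origin
  data.frame(sample_id = s$sample_id, chadha_x = x, chadha_y = y,
             chadha_field = field, boundary = boundary,
             stringsAsFactors = FALSE)
}

#' Combined facies assessment
#'
#' Gibbs ratios and zone plus Chadha coordinates and field per sample.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param basis Gibbs ratio basis, `"mass"` or `"meq"`.
#' @return Data frame, one row per sample.
#' @export
facies_assess <- function(ds, basis = c("mass", "meq")) {
  ds <- as_water_dataset(ds)
  g <- gibbs_ratios(ds, basis = basis)
  g$gibbs_zone <- classify_gibbs(g$cation_ratio, g$tds)
  ch <- chadha_classify(ds)
  cbind(g, ch[, c("chadha_x", "chadha_y", "chadha_field", "boundary")])
}

#' Chadha field frequency summary
#'
#' @param facies Output of [facies_assess()] or [chadha_classify()].
#' @return Data frame with counts per field 1--4 and the facies label.
#' @export
facies_summary <- function(facies) {
  labels <- c("Ca-HCO3", "Ca-Mg-Cl", "Na-Cl", "Na-HCO3")
  counts <- table(factor(facies$chadha_field, levels = 1:4))
  data.frame(chadha_field = 1:4, facies = labels,
             n = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(facies),
             stringsAsFactors = FALSE)
}
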