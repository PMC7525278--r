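#' @keywords internal
"_PACKAGE"

# Canonical parameter order used throughout the package.
.parameters <- c("ph", "ec", "tds", "cl", "so4", "hco3", "na", "k",
                 "ca", "mg", "zn", "co", "cu", "ni", "pb")
.optional_columns <- c("sample_id", "latitude", "longitude", "co3")

#' Assemble a validated water-sample dataset
#'
#' Bundles a per-sample measurement table with the parameter reference table
#' that downstream stages consult for units, guidelines and weights.
#' Validation enforces the physical invariants: concentrations nonnegative,
#' pH within \[0, 14\], every parameter present. Missing values must be
#' explicit `NA`s; the one documented default is carbonate (`co3`), taken as
#' 0 mg/L when the column is absent, since routine alkalinity titrations at
#' near-neutral pH report bicarbonate only.
#'
#' @param samples Data frame, one row per sample, with (case-insensitive)
#'   columns `ph, ec, tds, cl, so4, hco3, na, k, ca, mg, zn, co, cu, ni, pb`
#'   and optional `sample_id`, `latitude`, `longitude`, `co3`. Major ions in
#'   mg/L, trace metals in ug/L, EC in uS/cm.
#' @param specs Parameter reference table, default [who_parameter_table()].
#' @return An object of class `water_dataset`: a list with elements
#'   `samples` (canonicalised data frame) and `specs`.
#' @export
#' @examples
#' ds <- water_dataset(fixture_suite(1)$table1_means$samples)
#' descriptive_stats(ds)
water_dataset <- function(samples, specs = who_parameter_table()) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1)
  names(samples) <- tolower(trimws(names(samples)))
  missing_cols <- setdiff(.parameters, names(samples))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"co3" %in% names(samples)) samples$co3 <- 0
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- sprintf("S%02d", seq_len(nrow(samples)))
  }
  keep <- c("sample_id", intersect(c("latitude", "longitude"), names(samples)),
            .parameters, "co3")
  samples <- samples[, keep, drop = FALSE]
  for (p in c(.parameters, "co3")) {
    v <- samples[[p]]
    if (!is.numeric(v)) stop("column '", p, "' is not numeric", call. = FALSE)
    bad <- which(!is.na(v) & v < 0)
    if (p != "ph" && length(bad) > 0) {
      stop("negative concentration for '", p, "' in row(s): ",
           paste(samples$sample_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  ph_bad <- which(!is.na(samples$ph) & (samples$ph < 0 | samples$ph > 14))
  if (length(ph_bad) > 0) {
    stop("pH outside [0, 14] in row(s): ",
         paste(samples$sample_id[ph_bad], collapse = ", "), call. = FALSE)
  }
  missing_spec <- setdiff(.parameters, specs$parameter)
  if (length(missing_spec) > 0) {
    stop("specs table lacks parameter(s): ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  }
  structure(list(samples = samples, specs = specs), class = "water_dataset")
}

#' @export
print.water_dataset <- function(x, ...) {
  cat("<water_dataset> ", nrow(x$samples), " sample(s), ",
      length(.parameters), " parameters\n", sep = "")
  print(utils::head(x$samples, 6))
  invisible(x)
}

# Accept either a water_dataset or a raw samples data frame.
as_water_dataset <- function(x, specs = who_parameter_table()) {
  if (inherits(x, "water_dataset")) x else water_dataset(x, specs = specs)
}

#' Read a delimited sample table
#'
#' Reads a CSV or TSV file (delimiter autodetected from the header line
#' unless given) with one row per sample and case-insensitive column names.
#' Cells that fail numeric parsing are reported by row and column in a
#' warning and become `NA`; they are never dropped silently.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` (default) autodetects `","` vs `"\t"`.
#' @param specs Parameter reference table.
#' @return A `water_dataset`.
#' @export
read_samples <- function(path, sep = NULL, specs = who_parameter_table()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  names(raw) <- tolower(trimws(names(raw)))
  numeric_cols <- intersect(c(.parameters, "co3", "latitude", "longitude"),
                            names(raw))
  for (p in numeric_cols) {
    txt <- trimws(raw[[p]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & nzchar(txt) & txt != "NA")
    if (length(bad) > 0) {
      warning("unparseable numeric in column '", p, "', row(s) ",
              paste(bad, collapse = ", "), "; set to NA", call. = FALSE)
    }
    raw[[p]] <- val
  }
  water_dataset(raw, specs = specs)
}

#' Write a sample table as delimited text
#'
#' Inverse of [read_samples()]: values are written with six significant
#' digits so repeated runs produce byte-identical files.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param path Output file path.
#' @param sep Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_samples <- function(ds, path, sep = ",") {
  ds <- as_water_dataset(ds)
  out <- ds$samples
  for (p in names(out)) {
    if (is.numeric(out[[p]])) out[[p]] <- format_signif(out[[p]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Fixed-width-free numeric formatting: 6 significant digits, no padding.
format_signif <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g",
                                 digits = digits))
}

#' Convert a concentration from mg/L to meq/L
#'
#' Milliequivalents per litre normalise a mass concentration by the ion's
#' equivalent weight (molar mass / valence). The irrigation indices and the
#' Chadha coordinates are defined on this scale.
#'
#' @param value Concentration(s) in mg/L.
#' @param parameter Ion name (e.g. `"ca"`), matched against `constants`.
#' @param constants Valence/molar-mass table, default [ion_constants()].
#' @return Concentration(s) in meq/L.
#' @export
#' @examples
#' to_meq(40.08, "ca")  # 2 meq/L
to_meq <- function(value, parameter, constants = ion_constants()) {
  row <- constants[constants$parameter == tolower(parameter), , drop = FALSE]
  if (nrow(row) != 1 || is.na(row$valence) || row$valence == 0 ||
      is.na(row$molar_mass) || row$molar_mass <= 0) {
    stop("'", parameter, "' is not an ionic parameter", call. = FALSE)
  }
  value * row$valence / row$molar_mass
}

#' Per-parameter descriptive statistics
#'
#' Minimum, maximum, arithmetic mean, sample standard deviation (n-1
#' denominator) and standard error `se = sd/sqrt(n)` for every monitored
#' parameter. With a single sample, `sd` and `se` are reported as `NA`.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @return Data frame with one row per parameter.
#' @export
descriptive_stats <- function(ds) {
  ds <- as_water_dataset(ds)
  rows <- lapply(.parameters, function(p) {
    v <- ds$samples[[p]]
    v <- v[!is.na(v)]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(parameter = p, n = n,
               min = min(v), max = max(v), mean = mean(v),
               sd = s, se = s / sqrt(n), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of samples exceeding a guideline
#'
#' Strict comparison: a sample counts as exceeding only when its value is
#' strictly above the guideline (ties are compliant). For pH the guideline
#' is the two-sided range and exceedance means falling strictly outside it.
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param parameter Parameter name.
#' @return Fraction in \[0, 1\] (NAs excluded from both counts).
#' @export
exceedance_fraction <- function(ds, parameter) {
  ds <- as_water_dataset(ds)
  parameter <- tolower(parameter)
  spec <- ds$specs[ds$specs$parameter == parameter, , drop = FALSE]
  if (nrow(spec) != 1) stop("unknown parameter: ", parameter, call. = FALSE)
  v <- ds$samples[[parameter]]
  v <- v[!is.na(v)]
  if (!is.na(spec$si_lower)) {
    mean(v < spec$si_lower | v > spec$si)
  } else {
    mean(v > spec$si)
  }
}

#' Guideline screening summary
#'
#' One row per parameter: guideline, observed mean, and the fraction and
#' percentage of samples exceeding the guideline (two-sided for pH).
#'
#' @param ds A `water_dataset` or samples data frame.
#' @return Data frame.
#' @export
screen_guidelines <- function(ds) {
  ds <- as_water_dataset(ds)
  st <- descriptive_stats(ds)
  frac <- vapply(.parameters, function(p) exceedance_fraction(ds, p),
                 numeric(1))
  data.frame(
    parameter = .parameters,
    unit = ds$specs$unit[match(.parameters, ds$specs$parameter)],
    guideline = ds$specs$si[match(.parameters, ds$specs$parameter)],
    guideline_lower = ds$specs$si_lower[match(.parameters, ds$specs$parameter)],
    mean = st$mean[match(.parameters, st$parameter)],
    exceedance_fraction = unname(frac),
    exceedance_percent = unname(frac) * 100,
    stringsAsFactors = FALSE
  )
}
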