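#' Relative weights from assigned weights
#'
#' `Wi = wi / sum(wi)`; the result always sums to 1. Assigned weights are
#' integers from 1 (least health-critical) to 5 (most critical, e.g. Pb).
#'
#' @param weights Named numeric vector of assigned weights `wi`.
#' @return Named vector of relative weights summing to 1.
#' @export
#' @examples
#' relative_weights(c(a = 1, b = 3))
relative_weights <- function(weights) {
  if (length(weights) == 0) stop("empty weight map", call. = FALSE)
  if (any(!weights %in% 1:5)) {
    stop("assigned weights must be integers in 1..5", call. = FALSE)
  }
  weights / sum(weights)
}

#' Build a WQI weighting scheme
#'
#' Pairs each parameter with its guideline `si` and relative weight `Wi`.
#' Relative weights are recomputed from the integer assigned weights by
#' default; `use_printed_wi = TRUE` substitutes the relative-weight column
#' as printed in the source compilation (which does not sum to 1) for
#' comparison runs. The pH guideline is a range, so a single quotient
#' denominator must be chosen: the upper bound 8.5 by default
#' (configurable, e.g. 7.5 for the range midpoint).
#'
#' @param specs Parameter reference table, default [who_parameter_table()].
#' @param ph_si Guideline denominator used for pH (default 8.5).
#' @param use_printed_wi Use the printed relative-weight column verbatim.
#' @return Data frame of class `wqi_scheme` with columns `parameter`, `si`,
#'   `wi`, `Wi`.
#' @export
wqi_scheme <- function(specs = who_parameter_table(), ph_si = 8.5,
                       use_printed_wi = FALSE) {
  si <- specs$si
  si[specs$parameter == "ph"] <- ph_si
  Wi <- if (use_printed_wi) specs$printed_wi else
    unname(relative_weights(stats::setNames(specs$weight_wi, specs$parameter)))
  out <- data.frame(parameter = specs$parameter, si = si,
                    wi = specs$weight_wi, Wi = Wi, stringsAsFactors = FALSE)
  if (any(out$si <= 0)) stop("guidelines must be positive", call. = FALSE)
  class(out) <- c("wqi_scheme", "data.frame")
  out
}

#' Weighted-arithmetic Water Quality Index for one sample
#'
#' `WQI = sum(Wi * (Ci / Si) * 100)` over the scheme's parameters, where
#' `Ci` is the measured concentration, `Si` the guideline and `Wi` the
#' relative weight. Because the relative weights sum to 1, a sample sitting
#' exactly at every guideline scores 100.
#'
#' @param sample Named numeric vector (or one-row data frame) of measured
#'   concentrations covering every parameter in the scheme.
#' @param scheme A [wqi_scheme()].
#' @return List with `score`, `category` (see [classify_wqi()]) and the
#'   per-parameter `contributions` (which sum to the score).
#' @export
#' @examples
#' sch <- wqi_scheme()
#' at_guideline <- stats::setNames(sch$si, sch$parameter)
#' wqi_score(at_guideline, sch)$score  # 100
wqi_score <- function(sample, scheme = wqi_scheme()) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1)
    sample <- unlist(sample[intersect(names(sample), scheme$parameter)])
  }
  names(sample) <- tolower(names(sample))
  ci <- sample[scheme$parameter]
  missing <- scheme$parameter[is.na(ci)]
  if (length(missing) > 0) {
    stop("missing concentration for weighted parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contributions <- scheme$Wi * (as.numeric(ci) / scheme$si) * 100
  names(contributions) <- scheme$parameter
  score <- sum(contributions)
  list(score = score, category = classify_wqi(score),
       contributions = contributions)
}

#' Water Quality Index for every sample in a dataset
#'
#' @param ds A `water_dataset` or samples data frame.
#' @param scheme A [wqi_scheme()].
#' @return Data frame with `sample_id`, `score`, `category`.
#' @export
wqi <- function(ds, scheme = wqi_scheme()) {
  ds <- as_water_dataset(ds)
  scores <- vapply(seq_len(nrow(ds$samples)), function(i) {
    wqi_score(ds$samples[i, , drop = FALSE], scheme)$score
  }, numeric(1))
  data.frame(sample_id = ds$samples$sample_id, score = scores,
             category = classify_wqi(scores), stringsAsFactors = FALSE)
}

#' Potability category from a WQI score
#'
#' Lower-inclusive bands: below 50 excellent, \[50, 100) good, \[100, 200)
#' poor, \[200, 300) very poor, 300 and above unsuitable for drinking. The
#' published class list leaves 50--100 unnamed; the conventional "good"
#' band fills the gap (see the methods vignette).
#'
#' @param score Nonnegative WQI score(s).
#' @return Character vector of categories.
#' @export
classify_wqi <- function(score) {
  stopifnot(all(score >= 0, na.rm = TRUE))
  as.character(cut(score, breaks = c(-Inf, 50, 100, 200, 300, Inf),
                   labels = c("excellent", "good", "poor", "very poor",
                              "unsuitable"), right = FALSE))
}
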