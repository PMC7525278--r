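# ---- truncated normal machinery ------------------------------------------

# Mean and sd of a normal(mu, sigma) truncated to [a, b]. Tail-stable for
# strongly tilted cases (both truncation points far into one tail).
truncnorm_moments <- function(mu, sigma, a, b) {
  t1 <- (a - mu) / sigma
  t2 <- (b - mu) / sigma
  z <- if (t1 > 6) {
    stats::pnorm(t1, lower.tail = FALSE) - stats::pnorm(t2, lower.tail = FALSE)
  } else {
    stats::pnorm(t2) - stats::pnorm(t1)
  }
  if (!is.finite(z) || z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  d1 <- stats::dnorm(t1); d2 <- stats::dnorm(t2)
  m <- mu + sigma * (d1 - d2) / z
  v <- sigma^2 * (1 + (t1 * d1 - t2 * d2) / z - ((d1 - d2) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Location parameter hitting a target truncated mean at fixed sigma. The
# truncated mean is strictly increasing in mu, so bisection via uniroot is
# safe; brackets clamp at +-35 standardised units, beyond which the
# distribution is numerically degenerate at a boundary.
solve_truncnorm_mu <- function(sigma, a, b, target_mean) {
  f <- function(mu) truncnorm_moments(mu, sigma, a, b)[["mean"]] - target_mean
  lo <- a - 35 * sigma
  hi <- b + 35 * sigma
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || flo >= 0) return(lo)
  if (!is.finite(fhi) || fhi <= 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Moment-matched truncated normal parameters
#'
#' Finds parent parameters `(mu, sigma)` of a normal distribution truncated
#' to `[lower, upper]` whose truncated mean and standard deviation match the
#' targets. The mean is matched exactly (it is attainable for any target
#' strictly inside the interval). The sd is matched by a second root search
#' over `sigma`, along which the mean-matched truncated sd increases
#' monotonically toward a tilted-uniform supremum; when the target sd
#' exceeds that supremum (which happens for strongly skewed published
#' summaries) the fit returns the closest attainable sd and
#' `converged = FALSE`.
#'
#' @param mean,sd Target moments of the truncated distribution (`sd > 0`).
#' @param lower,upper Truncation bounds, `lower < mean < upper`.
#' @return List with `mu`, `sigma`, `lower`, `upper`, `attained_mean`,
#'   `attained_sd`, `converged`.
#' @export
fit_truncnorm <- function(mean, sd, lower, upper) {
  if (!(lower < mean && mean < upper)) {
    stop("infeasible marginal: mean must lie strictly inside [lower, upper]",
         call. = FALSE)
  }
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  width <- upper - lower
  # cap chosen so the location search (clamped at +-35 standardised units)
  # can always tilt far enough to hit the target mean; beyond ~5 widths the
  # truncated shape is already at its tilted-uniform limit and the
  # attainable sd gains nothing
  sigma_max <- 5 * width
  g <- function(sigma) {
    mu <- solve_truncnorm_mu(sigma, lower, upper, mean)
    truncnorm_moments(mu, sigma, lower, upper)[["sd"]] - sd
  }
  if (g(sigma_max) < 0) {
    sigma <- sigma_max
    converged <- FALSE
  } else {
    sigma <- stats::uniroot(g, c(1e-4 * width, sigma_max), tol = 1e-10)$root
    converged <- TRUE
  }
  mu <- solve_truncnorm_mu(sigma, lower, upper, mean)
  mm <- truncnorm_moments(mu, sigma, lower, upper)
  list(mu = mu, sigma = sigma, lower = lower, upper = upper,
       attained_mean = unname(mm[["mean"]]), attained_sd = unname(mm[["sd"]]),
       converged = converged)
}

# Inverse-CDF sampler for a fitted truncated normal.
rtruncnorm_fit <- function(n, fit) {
  t1 <- (fit$lower - fit$mu) / fit$sigma
  t2 <- (fit$upper - fit$mu) / fit$sigma
  if (t1 > 6) {
    # strongly tilted: sample in the upper-tail parameterisation for
    # numerical headroom, then reflect
    p1 <- stats::pnorm(t1, lower.tail = FALSE)
    p2 <- stats::pnorm(t2, lower.tail = FALSE)
    u <- stats::runif(n, min = p2, max = p1)
    q <- stats::qnorm(u, lower.tail = FALSE)
  } else {
    p1 <- stats::pnorm(t1)
    p2 <- stats::pnorm(t2)
    u <- stats::runif(n, min = p1, max = p2)
    q <- stats::qnorm(u)
  }
  pmin(pmax(fit$mu + fit$sigma * q, fit$lower), fit$upper)
}

# ---- correlation imposition ----------------------------------------------

# Nearest positive-semidefinite repair of a correlation matrix (only when
# needed).
repair_correlation <- function(r) {
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(r)
  as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
}

# Iman-Conover style rank reordering: each column of `x` is permuted so its
# ranks follow a correlated Gaussian reference with the target rank
# structure. Marginal sorted values are untouched (permutation only).
impose_rank_correlation <- function(x, target) {
  vars <- intersect(colnames(x), colnames(target))
  if (length(vars) < 2) return(x)
  tgt <- repair_correlation(target[vars, vars, drop = FALSE])
  n <- nrow(x)
  ref <- matrix(stats::rnorm(n * length(vars)), n) %*% chol(tgt)
  for (j in seq_along(vars)) {
    v <- vars[j]
    x[, v] <- sort(x[, v])[rank(ref[, j], ties.method = "first")]
  }
  x
}

# ---- generator ------------------------------------------------------------

#' Marginal specifications from the published summary table
#'
#' The default marginals of the synthetic generator: per parameter the
#' published minimum, maximum, mean and sd. Editable; pass a modified copy
#' to [generate_samples()].
#'
#' @return Data frame with columns `parameter`, `min`, `max`, `mean`, `sd`.
#' @export
table1_marginals <- function() {
  who_parameter_table()[, c("parameter", "min", "max", "mean", "sd")]
}

#' Generate a synthetic sample table
#'
#' Draws each parameter from a truncated normal on `[min, max]` whose
#' parent parameters are moment-matched to the marginal's mean and sd (see
#' [fit_truncnorm()]; for marginals whose published sd is unattainable
#' inside the truncated-normal family the closest attainable sd is used and
#' flagged). If a target correlation matrix is supplied, its rank structure
#' is imposed by distribution-preserving reordering against a correlated
#' Gaussian reference, leaving every marginal's sorted values untouched.
#' Identical seeds give bitwise-identical output.
#'
#' @param n Number of samples (default 30, the emulated survey size).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param marginals Marginal specification table, default
#'   [table1_marginals()].
#' @param target_correlation Optional symmetric correlation matrix with
#'   dimnames naming parameters (e.g. [default_target_correlation()]);
#'   repaired to the nearest positive-semidefinite matrix if needed.
#' @return A `water_dataset` when the marginals cover all fifteen monitored
#'   parameters, otherwise a plain list with element `samples`. The
#'   per-marginal fits (with convergence flags) are attached as
#'   `attr(ds, "fits")` and the seed as `attr(ds, "seed")`.
#' @export
#' @examples
#' ds <- generate_samples(30, seed = 42)
#' descriptive_stats(ds)
generate_samples <- function(n = 30, seed = NULL,
                             marginals = table1_marginals(),
                             target_correlation = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(nrow(marginals)), function(i) {
    m <- marginals[i, ]
    fit_truncnorm(m$mean, m$sd, m$min, m$max)
  })
  names(fits) <- marginals$parameter
  x <- vapply(fits, function(f) rtruncnorm_fit(n, f), numeric(n))
  if (n == 1) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(fits)))
  if (!is.null(target_correlation)) {
    colnames(target_correlation) <- tolower(colnames(target_correlation))
    rownames(target_correlation) <- tolower(rownames(target_correlation))
    x <- impose_rank_correlation(x, target_correlation)
  }
  samples <- as.data.frame(x)
  samples$sample_id <- sprintf("S%02d", seq_len(n))
  ds <- if (all(.parameters %in% names(samples))) {
    water_dataset(samples)
  } else {
    # partial marginal tables (single-parameter studies, tests) skip the
    # full-table validation but keep the same access pattern
    list(samples = samples)
  }
  attr(ds, "fits") <- fits
  attr(ds, "seed") <- seed
  ds
}

#' Deterministic fixture datasets
#'
#' A named collection of small datasets exercising every pipeline stage:
#' `table1_means` (a single sample sitting exactly at the published mean
#' concentrations -- the input of the summary-level risk assessment),
#' `n30_default` (30 seeded synthetic samples), `ca_hco3` and `na_cl`
#' (hydrochemical end-member waters for facies tests) and `degenerate`
#' (constant and near-zero columns).
#'
#' @param seed Seed for the synthetic component (default 1).
#' @return Named list of `water_dataset` objects.
#' @export
fixture_suite <- function(seed = 1) {
  means <- who_parameter_table()
  mean_row <- as.data.frame(as.list(stats::setNames(means$mean,
                                                    means$parameter)))
  mean_row$sample_id <- "MEAN"

  end_member <- function(id, ...) {
    base <- as.list(stats::setNames(rep(0, length(.parameters)), .parameters))
    base$ph <- 7
    over <- list(...)
    base[names(over)] <- over
    out <- as.data.frame(base)
    out$sample_id <- id
    out
  }
  # pure Ca-HCO3 water (field 1) and pure Na-Cl water (field 3); EC/TDS
  # set to small positive values so salinity classing stays defined
  ca_hco3 <- end_member("CAHCO3", ca = 40.08, hco3 = 122.04, ec = 200,
                        tds = 150)
  na_cl <- end_member("NACL", na = 22.99, cl = 35.45, ec = 200, tds = 150)

  degen <- data.frame(
    sample_id = c("D1", "D2", "D3"),
    ph = c(7, 7, 7), ec = c(100, 100, 100), tds = c(50, 50, 50),
    cl = c(10, 10, 10), so4 = c(5, 5, 5), hco3 = c(61.02, 61.02, 61.02),
    na = c(0, 0, 0), k = c(0, 0, 0), ca = c(20.04, 20.04, 20.04),
    mg = c(0, 0, 0), zn = c(1, 2, 3), co = c(0, 0, 0), cu = c(5, 5, 5),
    ni = c(10, 20, 30), pb = c(0, 1, 2), stringsAsFactors = FALSE
  )

  list(
    table1_means = water_dataset(mean_row),
    n30_default = generate_samples(30, seed = seed),
    ca_hco3 = water_dataset(ca_hco3),
    na_cl = water_dataset(na_cl),
    degenerate = water_dataset(degen)
  )
}
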