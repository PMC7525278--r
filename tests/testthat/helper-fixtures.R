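# Shared fixtures, built in code at load time.

fx <- fixture_suite(seed = 1)

# A tiny hand-checkable sample table (ions in mg/L chosen to give round
# meq/L values: equivalent weights Na 22.99, K 39.10, Ca 20.04, Mg 12.155,
# Cl 35.45, HCO3 61.02).
toy_samples <- function() {
  data.frame(
    sample_id = c("T1", "T2", "T3"),
    ph = c(7.0, 7.5, 8.0),
    ec = c(100, 426, 3000),
    tds = c(60, 228, 2000),
    cl = c(35.45, 70.90, 35.45),
    so4 = c(48.03, 96.06, 0),
    hco3 = c(61.02, 305.10, 61.02),
    na = c(22.99, 91.96, 45.98),
    k = c(39.10, 39.10, 0),
    ca = c(40.08, 160.32, 20.04),
    mg = c(24.31, 48.62, 12.155),
    zn = c(5, 15, 25),
    co = c(1, 2, 3),
    cu = c(10, 20, 30),
    ni = c(5, 15, 25),
    pb = c(1, 5, 12),
    stringsAsFactors = FALSE
  )
}

# Brute-force Pearson r from the covariance definition (independent of
# stats::cor).
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

# Brute-force partial correlation of variables i and j of `m` given the
# remaining columns, via residuals of least-squares fits.
brute_partial_cor <- function(m, i, j) {
  others <- setdiff(seq_len(ncol(m)), c(i, j))
  if (length(others) == 0) return(stats::cor(m[, i], m[, j]))
  ri <- stats::residuals(stats::lm(m[, i] ~ m[, others]))
  rj <- stats::residuals(stats::lm(m[, j] ~ m[, others]))
  stats::cor(ri, rj)
}

# Match a loading matrix to a reference up to column permutation and sign;
# returns the maximum absolute elementwise discrepancy of the best match.
loading_recovery_error <- function(est, ref) {
  k <- ncol(ref)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(k))) {
    e <- est[, p, drop = FALSE]
    for (s in seq_len(2^k)) {
      signs <- 2 * (as.integer(intToBits(s - 1))[1:k]) - 1
      err <- max(abs(sweep(e, 2, signs, `*`) - ref))
      best <- min(best, err)
    }
  }
  best
}
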