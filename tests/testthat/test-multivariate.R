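test_that("Pearson matrix equals the brute-force definition with valid p-values", {
  set.seed(11)
  m <- cbind(a = c(1, 4, 2, 8, 5), b = c(2, 3, 7, 6, 9),
             c = c(5, 1, 2, 2, 8))
  rep_ <- pearson_matrix(m, variables = c("a", "b", "c"))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(rep_$r[i, j], brute_pearson(m[, i], m[, j]),
                 tolerance = 1e-12)
  }
  # p from the t transform agrees with cor.test
  ct <- stats::cor.test(m[, 1], m[, 2])
  expect_equal(rep_$p[1, 2], ct$p.value, tolerance = 1e-10)
  expect_true(all(rep_$p >= 0 & rep_$p <= 1))
  expect_equal(rep_$r, t(rep_$r))
  expect_equal(unname(diag(rep_$r)), rep(1, 3))
})

test_that("collinear pairs hit r = 1 and independent columns stay near 0", {
  x <- seq_len(50)
  m <- cbind(a = x, b = 3 * x + 2, c = stats::rnorm(50))
  rep_ <- suppressWarnings(pearson_matrix(m, variables = c("a", "b", "c")))
  expect_equal(rep_$r["a", "b"], 1)
  expect_lt(rep_$p["a", "b"], 1e-10)
  set.seed(5)
  big <- matrix(stats::rnorm(1000 * 4), 1000,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  rep2 <- pearson_matrix(big, variables = c("w", "x", "y", "z"))
  off <- rep2$r[row(rep2$r) != col(rep2$r)]
  expect_true(all(abs(off) < 0.1))
})

test_that("constant columns are reported and produce undefined entries", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  expect_warning(rep_ <- pearson_matrix(m, variables = c("a", "b", "c")),
                 "constant column")
  expect_true(is.na(rep_$r["a", "b"]))
})

test_that("Bartlett sphericity matches its closed form", {
  # identity: ln det = 0 so chi2 = 0, p = 1
  b <- bartlett_sphericity(diag(4), n = 30)
  expect_equal(b$chi2, 0)
  expect_equal(b$df, 6)
  expect_equal(b$p_value, 1)
  # 2x2, r = 0.5, n = 30: chi2 = -(29 - 9/6) ln(0.75)
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  b <- bartlett_sphericity(r, n = 30)
  expect_equal(b$chi2, -(30 - 1 - (2 * 2 + 5) / 6) * log(1 - 0.25),
               tolerance = 1e-12)
  expect_equal(b$df, 1)
  # strongly correlated synthetic data is highly significant
  set.seed(3)
  z <- stats::rnorm(100)
  m <- cbind(z + stats::rnorm(100, sd = 0.3), z + stats::rnorm(100, sd = 0.3),
             z + stats::rnorm(100, sd = 0.3))
  bb <- bartlett_sphericity(stats::cor(m), n = 100)
  expect_lt(bb$p_value, 0.05)
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2), 10), "singular")
})

test_that("KMO matches the equal-correlation closed form and the oracle", {
  # 3x3 with equal off-diagonal r: partials are r/(1+r), so
  # KMO = (1+r)^2 / ((1+r)^2 + 1)
  for (r in c(0.2, 0.5, 0.8)) {
    R <- matrix(r, 3, 3); diag(R) <- 1
    expect_equal(kmo(R), (1 + r)^2 / ((1 + r)^2 + 1), tolerance = 1e-12)
  }
  expect_equal(kmo(matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3)),
               0.6923077, tolerance = 1e-6)
  # near-identity: r and q comparable, KMO near 0.5
  R <- diag(3); R[1, 2] <- R[2, 1] <- 1e-3
  expect_equal(kmo(R), 0.5, tolerance = 1e-3)
})

test_that("KMO equals the brute-force partial-correlation oracle on data", {
  set.seed(21)
  for (rep_i in 1:3) {
    z1 <- stats::rnorm(200); z2 <- stats::rnorm(200)
    m <- cbind(z1 + stats::rnorm(200, sd = 0.8),
               z1 + stats::rnorm(200, sd = 0.8),
               z2 + stats::rnorm(200, sd = 0.8),
               z2 + stats::rnorm(200, sd = 0.8))
    R <- stats::cor(m)
    q2 <- 0; r2 <- 0
    for (i in 1:3) for (j in (i + 1):4) {
      r2 <- r2 + 2 * R[i, j]^2
      q2 <- q2 + 2 * brute_partial_cor(m, i, j)^2
    }
    expect_equal(kmo(R), r2 / (r2 + q2), tolerance = 1e-10)
  }
})

test_that("block-structured strong correlations give an adequate KMO", {
  # three indicators per factor: within-block partial correlations shrink
  # to r/(1+r) while raw correlations stay high, lifting KMO above 0.6
  set.seed(33)
  z1 <- stats::rnorm(300); z2 <- stats::rnorm(300)
  m <- cbind(z1, z1, z1, z2, z2, z2) +
    matrix(stats::rnorm(300 * 6, sd = 0.6), 300)
  expect_gt(kmo(stats::cor(m)), 0.6)
})

test_that("PCA eigenvalues sum to the variable count and percentages to 100", {
  p <- pca_varimax(fx$n30_default)
  expect_equal(sum(p$eigenvalues), 12, tolerance = 1e-10)
  expect_equal(sum(p$variability_percent), 100, tolerance = 1e-10)
  expect_true(all(diff(p$cumulative_percent) >= -1e-12))
  expect_true(all(p$eigenvalues[seq_len(p$retained_k)] > 1))
})

test_that("varimax preserves communalities and rotation is orthogonal", {
  p <- pca_varimax(fx$n30_default)
  unrotated_comm <- rowSums(p$loadings^2)
  expect_lt(max(abs(p$communalities - unrotated_comm)), 1e-8)
  expect_equal(t(p$rotation) %*% p$rotation, diag(p$retained_k),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each factor positive
  peaks <- apply(p$rotated_loadings, 2, function(cl) cl[which.max(abs(cl))])
  expect_true(all(peaks > 0))
})

test_that("rotated solution is invariant to variable order up to sign/permutation", {
  vars <- c("ph", "ec", "tds", "na", "k", "ca", "mg", "zn", "co", "cu",
            "ni", "pb")
  p1 <- pca_varimax(fx$n30_default, variables = vars)
  for (seed in c(101, 202)) {
    set.seed(seed)
    shuffled <- sample(vars)
    p2 <- pca_varimax(fx$n30_default, variables = shuffled)
    expect_equal(p2$retained_k, p1$retained_k)
    l1 <- p1$rotated_loadings
    l2 <- p2$rotated_loadings[rownames(l1), , drop = FALSE]
    expect_lt(loading_recovery_error(l2, l1), 1e-6)
  }
})

test_that("a flat eigenvalue spectrum triggers the retention warning", {
  set.seed(9)
  m <- matrix(stats::rnorm(2000 * 5), 2000,
              dimnames = list(NULL, letters[1:5]))
  expect_warning(pca_varimax(m, variables = letters[1:5]), "flat eigenvalue")
})
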