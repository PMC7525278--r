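# Default variable set for the source-apportionment stage: the metals and
# the physicochemical drivers that are carried through the correlation and
# PCA tables (anions are screened separately).
.stat_variables <- c("ph", "ec", "tds", "na", "k", "ca", "mg",
                     "zn", "co", "cu", "ni", "pb")

# Extract a numeric matrix of the requested variables from a dataset,
# data frame or matrix.
stat_matrix <- function(x, variables = NULL) {
  if (inherits(x, "water_dataset")) x <- x$samples
  x <- as.data.frame(x)
  names(x) <- tolower(names(x))
  if (is.null(variables)) {
    variables <- intersect(.stat_variables, names(x))
    if (length(variables) == 0) variables <- names(x)[vapply(x, is.numeric, logical(1))]
  } else {
    variables <- tolower(variables)
    missing <- setdiff(variables, names(x))
    if (length(missing) > 0) {
      stop("unknown variable(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  as.matrix(x[, variables, drop = FALSE])
}

#' Pearson correlation matrix with two-tailed significance flags
#'
#' Pairwise Pearson coefficients with two-tailed p-values from the exact t
#' transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom,
#' and star flags at the 0.05 and 0.01 levels. Constant columns produce
#' undefined (`NA`) entries with a warning.
#'
#' @param x A `water_dataset`, data frame or numeric matrix.
#' @param variables Variables to correlate; defaults to the metals plus
#'   pH/EC/TDS and major cations when present.
#' @return List of class `correlation_report` with elements `r`, `p`,
#'   `sig05`, `sig01`, `n`.
#' @export
pearson_matrix <- function(x, variables = NULL) {
  m <- stat_matrix(x, variables)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  constant <- apply(m, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(constant)) {
    warning("constant column(s): ",
            paste(colnames(m)[constant], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(r = r, p = p, sig05 = p < 0.05 & row(p) != col(p),
                 sig01 = p < 0.01 & row(p) != col(p), n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("<correlation_report> n =", x$n, "\n")
  stars <- ifelse(x$sig01, "**", ifelse(x$sig05, "*", ""))
  out <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), stars),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is an identity matrix (variables
#' unrelated):
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom. A significant result supports factoring the matrix.
#'
#' @param r Correlation matrix (positive definite).
#' @param n Number of observations behind `r`.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(r, n) {
  p <- ncol(r)
  d <- det(r)
  if (!is.finite(d) || d <= 0) {
    stop("correlation matrix is singular or not positive definite ",
         "(condition number ", formatC(kappa(r), format = "e", digits = 2),
         ")", call. = FALSE)
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal entries,
#' where `q` are the partial correlations obtained from the scaled inverse
#' of the correlation matrix (anti-image correlations). Values near 1
#' indicate the correlation structure is dominated by shared factors;
#' values toward 0.5 and below indicate diffuse partial correlations.
#'
#' @param r Correlation matrix (invertible).
#' @return Overall KMO in (0, 1\].
#' @export
kmo <- function(r) {
  inv <- tryCatch(solve(r), error = function(e) {
    stop("correlation matrix is singular; KMO undefined", call. = FALSE)
  })
  s <- diag(1 / sqrt(diag(inv)))
  q <- -s %*% inv %*% s   # partial (anti-image) correlations
  off <- row(r) != col(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(q[off]^2))
}

#' Correlation-matrix PCA with varimax rotation
#'
#' Standardises the variables, eigendecomposes their correlation matrix,
#' retains components with eigenvalue above 1 (Kaiser criterion), and
#' varimax-rotates the retained loading matrix (Kaiser-normalised,
#' convergence tolerance 1e-6). Each rotated factor is sign-flipped so its
#' largest-magnitude loading is positive, and factors are ordered by
#' decreasing explained variance. KMO and Bartlett diagnostics are
#' computed on the same correlation matrix.
#'
#' The eigenvalues of a correlation matrix sum to the number of variables,
#' so per-component variance percentages sum to 100. When the eigenvalue
#' spectrum is nearly flat (no component separates from 1), retention under
#' the Kaiser rule is unstable and a warning is issued.
#'
#' @param x A `water_dataset`, data frame or numeric matrix.
#' @param variables Variables to include (default as [pearson_matrix()]).
#' @param eigenvalue_cutoff Retention threshold (default 1).
#' @return List of class `pca_report`: `eigenvalues`, `variability_percent`,
#'   `cumulative_percent`, `retained_k`, `loadings` (unrotated, retained),
#'   `rotated_loadings`, `rotation`, `communalities`, `kmo`, `bartlett`,
#'   `n`.
#' @export
pca_varimax <- function(x, variables = NULL, eigenvalue_cutoff = 1) {
  m <- stat_matrix(x, variables)
  n <- nrow(m)
  r <- stats::cor(m)
  eig <- eigen(r, symmetric = TRUE)
  values <- eig$values
  p <- ncol(r)
  variability <- 100 * values / p
  k <- sum(values > eigenvalue_cutoff)
  if (k < 1) stop("no component exceeds the eigenvalue cut-off", call. = FALSE)
  if (max(values) - min(values) < 0.5) {
    warning("nearly flat eigenvalue spectrum; Kaiser retention unstable",
            call. = FALSE)
  }
  loadings <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(values[seq_len(k)]), k)
  dimnames(loadings) <- list(colnames(r), paste0("F", seq_len(k)))
  if (k >= 2) {
    vm <- stats::varimax(loadings, normalize = TRUE, eps = 1e-6)
    rotated <- loadings %*% vm$rotmat
    rotation <- vm$rotmat
  } else {
    rotated <- loadings
    rotation <- diag(1)
  }
  # sign convention: largest-magnitude loading per factor positive
  flips <- apply(rotated, 2, function(col) sign(col[which.max(abs(col))]))
  flips[flips == 0] <- 1
  rotated <- sweep(rotated, 2, flips, `*`)
  rotation <- sweep(rotation, 2, flips, `*`)
  # order factors by decreasing explained variance after rotation
  ssl <- colSums(rotated^2)
  ord <- order(ssl, decreasing = TRUE)
  rotated <- rotated[, ord, drop = FALSE]
  rotation <- rotation[, ord, drop = FALSE]
  ssl <- ssl[ord]
  colnames(rotated) <- paste0("F", seq_len(k))
  structure(list(
    eigenvalues = values,
    variability_percent = variability,
    cumulative_percent = cumsum(variability),
    retained_k = k,
    loadings = loadings,
    rotated_loadings = rotated,
    rotation = rotation,
    rotated_variability_percent = 100 * ssl / p,
    communalities = rowSums(rotated^2),
    kmo = kmo(r),
    bartlett = bartlett_sphericity(r, n),
    n = n
  ), class = "pca_report")
}

#' @export
print.pca_report <- function(x, digits = 2, ...) {
  cat("<pca_report> n =", x$n, "; retained", x$retained_k,
      "component(s) with eigenvalue > 1\n")
  cat("KMO =", formatC(x$kmo, digits = 3, format = "f"),
      "; Bartlett chi2 =", formatC(x$bartlett$chi2, digits = 2, format = "f"),
      "(df", x$bartlett$df, ", p =",
      formatC(x$bartlett$p_value, digits = 3, format = "g"), ")\n")
  cat("cumulative variance of retained components:",
      formatC(x$cumulative_percent[x$retained_k], digits = 1, format = "f"),
      "%\n")
  print(round(x$rotated_loadings, digits))
  invisible(x)
}
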