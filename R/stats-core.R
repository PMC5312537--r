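# Shared statistical primitives used by every pipeline stage.

#' Pearson correlation with t-distribution p-value
#'
#' Computes the Pearson product-moment correlation between two numeric
#' vectors and the two-sided p-value from the t-distribution transform of
#' the coefficient, as used for ion-intensity vs donor-age associations.
#'
#' @param x,y Numeric vectors of equal length (at least 3), both
#'   non-constant.
#' @param feature Optional label used in error messages when the
#'   correlation is undefined (constant input).
#' @return A list with elements `rho` (in \[-1, 1\]) and `p` (two-sided).
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearson_correlation <- function(x, y, feature = NULL) {
  .check_cor_input(x, y, feature)
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' The coefficient is the Pearson correlation of the (tie-averaged) ranks;
#' the two-sided p-value uses the usual t-transform of the rank
#' correlation. Used for enzyme-metabolite coupling and gene-age trends.
#'
#' @inheritParams pearson_correlation
#' @return A list with elements `rho` and `p`.
#' @export
spearman_correlation <- function(x, y, feature = NULL) {
  .check_cor_input(x, y, feature)
  pearson_correlation(rank(x), rank(y), feature = feature)
}

.check_cor_input <- function(x, y, feature) {
  if (length(x) != length(y)) {
    stop("correlation inputs must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("correlation requires at least 3 paired observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("correlation inputs must not contain missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    lab <- if (is.null(feature)) "input" else paste0("feature '", feature, "'")
    stop("undefined correlation: ", lab, " is constant", call. = FALSE)
  }
  invisible(TRUE)
}

#' Welch's unpaired heteroscedastic t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption,
#' with Welch-Satterthwaite degrees of freedom. Degenerate inputs in
#' which both groups have zero variance are rejected rather than
#' returning an infinite or undefined statistic.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return A list with elements `t`, `df` and `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("t statistic undefined: both groups have zero variance",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, capped at 1, order-preserving.
#' @export
bh_adjust <- function(p) {
  .check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with fixed-lambda pi0 estimate
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * n))` and returns
#' `pi0` times the Benjamini-Hochberg cumulative-minimum transform. The
#' q-value family must be the full set of tested features; never adjust
#' per-feature.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning threshold in (0, 1) for the pi0 estimate
#'   (default 0.5).
#' @return q-values in \[0, 1\], monotone in `p`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  .check_pvalues(p)
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda <= 0 || lambda >= 1) {
    stop("lambda must be a single value in (0, 1)", call. = FALSE)
  }
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * length(p)))
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

.check_pvalues <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (anyNA(p)) stop("p-values must not contain NA", call. = FALSE)
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Quantile normalization of an intensity or expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the row means of the column-sorted matrix. Ties within a
#' column receive the mean of the reference values at their tied ranks.
#' Missing values are rejected: imputation is out of scope.
#'
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("matrix must be numeric", call. = FALSE)
  if (anyNA(mat)) {
    stop("quantile normalization requires a complete matrix (no NA)",
         call. = FALSE)
  }
  if (ncol(mat) < 1L) stop("need at least one sample column", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2 fold change as a mean difference on log2 scale
#'
#' @param old,young Numeric vectors of log2-scale values for the two
#'   groups; the result is `mean(old) - mean(young)`.
#' @return A single numeric log2 fold change.
#' @export
log2_fold_change <- function(old, young) {
  if (length(old) == 0L || length(young) == 0L) {
    stop("fold change requires non-empty groups", call. = FALSE)
  }
  mean(old) - mean(young)
}

# Vectorized two-sided p for a correlation coefficient via the
# t-transform (n - 2 df); mirrors cor.test's asymptotic path. Rows with
# |r| numerically 1 get p = 0.
.cor_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  denom <- 1 - r^2
  p <- rep(0, length(r))
  ok <- denom > .Machine$double.eps
  tstat <- r[ok] * sqrt((n - 2) / denom[ok])
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

# Row-wise Spearman correlation of each row of X against each row of Y
# (matched sample columns), with t-approximation p-values. Constant rows
# yield rho = NA.
.spearman_matrix <- function(X, Y) {
  stopifnot(ncol(X) == ncol(Y))
  n <- ncol(X)
  rx <- t(apply(X, 1L, rank))
  ry <- t(apply(Y, 1L, rank))
  C <- suppressWarnings(stats::cor(t(rx), t(ry)))
  P <- matrix(.cor_pvalue(as.vector(C), n), nrow = nrow(C),
              dimnames = dimnames(C))
  P[is.na(C)] <- NA_real_
  list(rho = C, p = P)
}

# Row-wise Spearman correlation of each row of X against a single
# covariate (e.g. donor age).
.spearman_rows_vs <- function(X, y) {
  res <- .spearman_matrix(X, matrix(y, nrow = 1L))
  list(rho = as.vector(res$rho), p = as.vector(res$p))
}
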