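# Network locality scoring: each metabolic enzyme is scored by the
# weighted mean of the absolute Spearman correlation between its
# transcript and the surrounding metabolites, weights decaying with the
# squared network distance, and significance is assessed against
# permuted versions of the distance matrix.

# Locality weights: D^-2 * (1 - p_C), zero for unreachable metabolites
# or those beyond d_max.
.locality_weights <- function(D, pC, d_max = Inf) {
  w <- D^-2 * (1 - pC)
  w[!is.finite(D) | D > d_max] <- 0
  w
}

#' Locality score for one transcript
#'
#' `S = sum(D^-2 (1 - p_C) |C|) / sum(D^-2 (1 - p_C))` over the
#' metabolites with finite network distance at most `d_max`: a weighted
#' mean of absolute Spearman correlations, so S lies in \[0, 1\] and
#' equals |C| when the neighborhood has a single member.
#'
#' @param C Numeric vector of Spearman correlations between the
#'   transcript and each metabolite.
#' @param pC Numeric vector of the correlations' p-values.
#' @param D Numeric vector of network distances (Inf = unreachable).
#' @param d_max Neighborhood radius; Inf (default) uses all reachable
#'   metabolites, with the squared-distance decay bounding influence.
#' @return The locality score, a single number in \[0, 1\].
#' @export
locality_score <- function(C, pC, D, d_max = Inf) {
  stopifnot(length(C) == length(pC), length(C) == length(D))
  w <- .locality_weights(D, pC, d_max)
  total <- sum(w)
  if (total == 0) {
    stop("empty neighborhood: no metabolite with finite distance <= d_max",
         call. = FALSE)
  }
  sum(w * abs(C)) / total
}

# Scores for all transcripts at once given a weight matrix.
.locality_scores_all <- function(W, absC) {
  num <- rowSums(W * absC)
  den <- rowSums(W)
  ifelse(den > 0, num / den, NA_real_)
}

#' Locality scores with distance-permutation p-values
#'
#' Computes per-transcript Spearman correlations against all measured
#' network metabolites, the locality score S, and a permutation
#' p-value: for each of K iterations one random permutation of the
#' metabolite indices (shared across transcripts) is applied to the
#' columns of the distance matrix, the scores are recomputed with the
#' correlations held fixed, and `p = #\{S_rand >= S\} / K`. A transcript
#' whose neighborhood is empty after a permutation skips that
#' iteration (its K is reduced and logged).
#'
#' @param expr Gene-collapsed log2 expression matrix (enzymes x
#'   samples) for the transcripts to score.
#' @param metab Metabolite profile matrix (metabolites x samples),
#'   samples matched to `expr`.
#' @param D Distance matrix from [enzyme_metabolite_distances()], rows
#'   covering the rows of `expr`, columns the rows of `metab`.
#' @param K Number of permutations (default 10000).
#' @param d_max Neighborhood radius (default Inf).
#' @param seed Optional seed for the permutation stream.
#' @return data.frame: `transcript`, `S`, `p_locality`, `K`,
#'   `n_neighbors`; the correlation and p matrices are attached as
#'   attributes `C` and `pC` for reporting.
#' @export
locality_test <- function(expr, metab, D, K = 10000, d_max = Inf,
                          seed = NULL) {
  stopifnot(ncol(expr) == ncol(metab))
  .check_count(K, "K")
  D <- D[rownames(expr), rownames(metab), drop = FALSE]
  cors <- .spearman_matrix(expr, metab)
  C <- cors$rho
  pC <- cors$p
  # constant profiles have no defined correlation; they contribute
  # nothing to the score
  undef <- is.na(C)
  if (any(undef)) {
    C[undef] <- 0
    pC[undef] <- 1
  }
  absC <- abs(C)
  W0 <- .locality_weights(D, pC, d_max)
  S <- .locality_scores_all(W0, absC)
  skipped <- which(is.na(S))
  if (length(skipped) > 0L) {
    ml_log("WARN", sprintf("%d transcript(s) skipped: empty neighborhood",
                           length(skipped)))
  }
  M <- ncol(D)
  exceed <- numeric(nrow(D))
  k_eff <- integer(nrow(D))
  .with_seed(seed, {
    for (k in seq_len(K)) {
      perm <- sample.int(M)
      W <- .locality_weights(D[, perm, drop = FALSE], pC, d_max)
      Sk <- .locality_scores_all(W, absC)
      valid <- !is.na(Sk) & !is.na(S)
      k_eff <- k_eff + valid
      exceed <- exceed + (valid & Sk >= S - 1e-12)
    }
  })
  reduced <- !is.na(S) & k_eff < K
  if (any(reduced)) {
    ml_log("WARN", sprintf("%d transcript(s) had permutations skipped",
                           sum(reduced)))
  }
  p <- ifelse(k_eff > 0, exceed / k_eff, NA_real_)
  out <- data.frame(
    transcript = rownames(D),
    S = S,
    p_locality = p,
    K = k_eff,
    n_neighbors = rowSums(W0 > 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "C") <- C
  attr(out, "pC") <- pC
  out
}

#' Filter locality results to age-dependent functional hits
#'
#' Retains transcripts with a significant locality score
#' (`p_locality < p_locality_max`) that also show an age-dependent
#' expression change: Spearman gene-age correlation p below
#' `p_age_max`, or BH-adjusted differential p below `adjp_max`. Output
#' is sorted by `p_locality` ascending.
#'
#' @param results data.frame joining per-transcript locality and
#'   transcriptomic statistics; must contain `p_locality`, `p_age` and
#'   `adj_p`.
#' @param p_locality_max Locality significance gate (default 0.05).
#' @param p_age_max Gene-age correlation gate (default 0.1).
#' @param adjp_max Differential-expression gate (default 0.1).
#' @return The retained rows, ordered by `p_locality`.
#' @export
filter_locality_hits <- function(results, p_locality_max = 0.05,
                                 p_age_max = 0.1, adjp_max = 0.1) {
  stopifnot(all(c("p_locality", "p_age", "adj_p") %in% names(results)))
  loc_ok <- !is.na(results$p_locality) & results$p_locality < p_locality_max
  age_ok <- (!is.na(results$p_age) & results$p_age < p_age_max) |
    (!is.na(results$adj_p) & results$adj_p < adjp_max)
  out <- results[loc_ok & age_ok, , drop = FALSE]
  out <- out[order(out$p_locality), , drop = FALSE]
  rownames(out) <- NULL
  out
}
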