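# Transcriptome stage: QC filtering, normalization, two-group
# differential expression with BH control, gene-age Spearman trends,
# and restriction to metabolic genes.

#' Remove features dominated by saturated or background signal
#'
#' A feature is removed iff its flagged fraction (saturated or
#' background cells over all samples) is at least `max_bad_fraction`;
#' the boundary is inclusive, matching an "in at least 50% of the
#' cases" rule.
#'
#' @param expr Expression matrix, features x samples.
#' @param flags Character matrix of per-cell QC flags (`"ok"`,
#'   `"saturated"`, `"background"`), same shape as `expr`. NULL means
#'   all-ok.
#' @param max_bad_fraction Removal threshold (default 0.5).
#' @return The filtered expression matrix; removed feature ids in
#'   attribute `"removed"`.
#' @export
qc_filter_features <- function(expr, flags = NULL, max_bad_fraction = 0.5) {
  if (is.null(flags)) return(structure(expr, removed = character(0)))
  stopifnot(identical(dim(flags), dim(expr)))
  bad_frac <- rowMeans(flags != "ok")
  removed <- rownames(expr)[bad_frac >= max_bad_fraction]
  ml_log("INFO", sprintf("QC filter: %d of %d features removed (>=%.0f%% flagged)",
                         length(removed), nrow(expr), 100 * max_bad_fraction))
  structure(expr[bad_frac < max_bad_fraction, , drop = FALSE],
            removed = removed)
}

# Row variances without matrixStats.
.row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Two-group differential expression with age trends
#'
#' Per-feature ordinary linear model on the group indicator (identical
#' to the pooled-variance two-sample t-test), log2 fold change as the
#' group coefficient (old minus young), Benjamini-Hochberg adjustment
#' over all retained features, plus the Spearman correlation of each
#' feature with donor age used later by the locality hit filter.
#' No empirical-Bayes variance moderation is applied; with ~2x23
#' arrays the ordinary and moderated statistics differ negligibly and
#' the ordinary model keeps the procedure fully explicit.
#'
#' @param expr Quantile-normalized log2 expression, features x samples.
#' @param donors Donor table (`sample_id`, `age`, `group`).
#' @return data.frame: `feature_id`, `log2fc`, `t`, `p`, `adj_p`,
#'   `rho_age`, `p_age`.
#' @export
differential_expression <- function(expr, donors) {
  expr <- .match_samples(expr, donors, "expression matrix")
  old <- donors$group == "old"
  n1 <- sum(old)
  n2 <- sum(!old)
  if (n1 < 2L || n2 < 2L) {
    stop("each donor group needs at least 2 samples", call. = FALSE)
  }
  xo <- expr[, old, drop = FALSE]
  xy <- expr[, !old, drop = FALSE]
  fc <- rowMeans(xo) - rowMeans(xy)
  sp2 <- ((n1 - 1) * .row_vars(xo) + (n2 - 1) * .row_vars(xy)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, fc / se, NA_real_)
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  adj_p <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance feature(s) excluded from the ",
            "adjustment family", call. = FALSE)
  }
  adj_p[ok] <- bh_adjust(p[ok])
  age <- .spearman_rows_vs(expr, donors$age)
  data.frame(
    feature_id = rownames(expr),
    log2fc = fc, t = tt, p = p, adj_p = adj_p,
    rho_age = age$rho, p_age = age$p,
    stringsAsFactors = FALSE
  )
}

#' Select differentially expressed transcripts
#'
#' The published rule: BH-adjusted p strictly below `p_max` and
#' |log2(FC)| strictly greater than `fc_min` (defaults 0.01 and 0.25).
#'
#' @param results Output of [differential_expression()].
#' @param fc_min,p_max Significance thresholds.
#' @return data.frame of passing features with a `direction` column.
#' @export
significant_transcripts <- function(results, fc_min = 0.25, p_max = 0.01) {
  keep <- !is.na(results$adj_p) & abs(results$log2fc) > fc_min &
    results$adj_p < p_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Restrict features to metabolic genes
#'
#' Keeps the features whose gene symbol is a member of at least one
#' metabolic pathway; symbols absent from the map are counted and
#' logged, never an error.
#'
#' @param features Character vector of gene symbols (or a data.frame
#'   with a `feature_id` column).
#' @param gene_pathway_map data.frame with columns `pathway_id` and
#'   `member_id` (gene symbols).
#' @return The metabolic subset, same type as the input.
#' @export
map_to_metabolic_genes <- function(features, gene_pathway_map) {
  ids <- if (is.data.frame(features)) features$feature_id else features
  metabolic <- ids %in% unique(gene_pathway_map$member_id)
  ml_log("INFO", sprintf("metabolic-gene map: %d of %d features mapped",
                         sum(metabolic), length(ids)))
  if (is.data.frame(features)) {
    features[metabolic, , drop = FALSE]
  } else {
    features[metabolic]
  }
}

#' Collapse probes to one representative feature per gene
#'
#' When several features share a gene symbol, the feature with the
#' largest mean expression represents the gene (used for the locality
#' analysis, which works at gene level).
#'
#' @param expr Expression matrix, features x samples.
#' @param gene_map Named character vector: feature id -> gene symbol.
#' @return Expression matrix with one row per gene, rownames set to
#'   gene symbols.
#' @export
collapse_probes_to_genes <- function(expr, gene_map) {
  gene <- unname(gene_map[rownames(expr)])
  if (anyNA(gene)) {
    stop("gene_map is missing symbols for some features", call. = FALSE)
  }
  keep <- tapply(seq_len(nrow(expr)), gene, function(idx) {
    idx[which.max(rowMeans(expr[idx, , drop = FALSE]))]
  })
  out <- expr[as.integer(keep), , drop = FALSE]
  rownames(out) <- names(keep)
  out
}
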