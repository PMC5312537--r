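# Recursive nested-subset hypergeometric pathway enrichment: the
# hypergeometric test is evaluated on every significance-ordered prefix
# of the hit list and the best (minimum) p is reported per pathway.

#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= ptw_hits) for X hypergeometric with `ptw_all` pathway members
#' among `total_all` detected features and `total_hits` draws (the hit
#' subset). The point mass of this law is the classical enrichment
#' term; a point mass alone is not a p-value, so the upper tail is the
#' test statistic. `pmf_only = TRUE` returns the literal single term
#' instead.
#'
#' @param ptw_hits Hits that belong to the pathway.
#' @param total_all Number of detected features (background).
#' @param ptw_all Pathway members among the detected features.
#' @param total_hits Size of the hit subset.
#' @param pmf_only Return the point mass P(X = ptw_hits) instead of the
#'   tail.
#' @return A probability in \[0, 1\].
#' @export
hypergeometric_tail <- function(ptw_hits, total_all, ptw_all, total_hits,
                                pmf_only = FALSE) {
  counts <- c(ptw_hits, total_all, ptw_all, total_hits)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (ptw_all > total_all || total_hits > total_all ||
      ptw_hits > min(ptw_all, total_hits)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (pmf_only) {
    return(stats::dhyper(ptw_hits, ptw_all, total_all - ptw_all, total_hits))
  }
  stats::phyper(ptw_hits - 1, ptw_all, total_all - ptw_all, total_hits,
                lower.tail = FALSE)
}

# Normalize a pathway definition (data.frame pathway_id/member_id or a
# named list of member vectors) to a named list.
.as_pathway_list <- function(pathways) {
  if (is.data.frame(pathways)) {
    stopifnot(all(c("pathway_id", "member_id") %in% names(pathways)))
    pathways <- split(pathways$member_id, pathways$pathway_id)
  }
  if (is.null(names(pathways)) || any(names(pathways) == "")) {
    stop("pathways must be named", call. = FALSE)
  }
  lapply(pathways, unique)
}

#' Recursive prefix enrichment over a ranked hit list
#'
#' For each pathway, the hypergeometric upper tail is evaluated on
#' every prefix of the significance-ordered hit list -- first the single
#' most significant feature, then the two best, and so on until the
#' full significant set -- and the minimum p over prefixes is reported
#' together with the prefix size achieving it. Pathway membership is
#' always intersected with the detected background.
#'
#' @param ranked_hits Character vector of significant feature ids,
#'   ordered most-significant first; must be unique and a subset of
#'   `background`.
#' @param pathways Named list of member-id vectors, or a data.frame
#'   with `pathway_id`/`member_id` columns.
#' @param background Character vector of all detected feature ids.
#' @param pmf_only Use the literal point-mass term instead of the tail.
#' @return data.frame: `pathway_id`, `best_p`, `best_subset_size`,
#'   `ptw_all` (members in background), `ptw_hits` (members in the full
#'   hit set).
#' @export
recursive_enrichment <- function(ranked_hits, pathways, background,
                                 pmf_only = FALSE) {
  pw <- .as_pathway_list(pathways)
  background <- unique(background)
  if (anyDuplicated(ranked_hits)) {
    stop("ranked_hits must be unique", call. = FALSE)
  }
  if (!all(ranked_hits %in% background)) {
    stop("ranked_hits must be a subset of the background", call. = FALSE)
  }
  if (length(ranked_hits) == 0L) {
    warning("empty hit list: no enrichment computed", call. = FALSE)
    return(data.frame(pathway_id = character(0), best_p = numeric(0),
                      best_subset_size = integer(0), ptw_all = integer(0),
                      ptw_hits = integer(0), stringsAsFactors = FALSE))
  }
  n_all <- length(background)
  n_hits <- length(ranked_hits)
  prefix_sizes <- seq_len(n_hits)
  res <- lapply(names(pw), function(id) {
    members <- intersect(pw[[id]], background)
    ptw_all <- length(members)
    cum_hits <- cumsum(ranked_hits %in% members)
    p_prefix <- stats::phyper(cum_hits - 1, ptw_all, n_all - ptw_all,
                              prefix_sizes, lower.tail = FALSE)
    if (pmf_only) {
      p_prefix <- stats::dhyper(cum_hits, ptw_all, n_all - ptw_all,
                                prefix_sizes)
    }
    best <- which.min(p_prefix)
    data.frame(pathway_id = id, best_p = p_prefix[best],
               best_subset_size = best, ptw_all = ptw_all,
               ptw_hits = cum_hits[n_hits], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Storey correction and significance flag for enrichment results
#'
#' @param results Output of [recursive_enrichment()].
#' @param lambda Storey pi0 tuning parameter (default 0.5).
#' @param q_max Significance threshold on q (default 0.01).
#' @return `results` with columns `q` and `significant`, ordered by
#'   `best_p`.
#' @export
enrichment_fdr <- function(results, lambda = 0.5, q_max = 0.01) {
  if (nrow(results) == 0L) {
    results$q <- numeric(0)
    results$significant <- logical(0)
    return(results)
  }
  results$q <- storey_qvalues(results$best_p, lambda = lambda)
  results$significant <- results$q < q_max
  out <- results[order(results$best_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
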