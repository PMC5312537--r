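# Metabolome stage: exact-mass ion annotation, normalization, and
# age-association / old-vs-young differential statistics with the
# published significance filters.

# Negative-mode adduct shifts in Da relative to the neutral
# monoisotopic mass: [M-H]- loses a proton, [M+F]- gains a fluoride.
.ADDUCT_SHIFTS <- c("M-H" = -1.007276, "M+F" = 18.998403)

#' Annotate ions by exact mass
#'
#' Matches each observed ion m/z against the adduct masses of the
#' supplied compound database: a compound M is a candidate for an ion
#' when |observed m/z - (M + shift)| <= tolerance, with shift -1.007276
#' Da for \[M-H\]- and +18.998403 Da for \[M+F\]-. Ions without a
#' candidate stay unannotated but remain in all downstream statistics
#' as detected ions.
#'
#' @param mz Named numeric vector of observed ion m/z (names are ion
#'   ids).
#' @param db Compound table with columns `compound_id` and `mass`
#'   (neutral monoisotopic, Da).
#' @param tolerance Mass accuracy in Da (default 0.001, must be > 0).
#' @param adducts Adducts to consider, subset of `c("M-H", "M+F")`.
#' @return data.frame with one row per (ion, compound, adduct) match:
#'   `ion_id`, `compound_id`, `adduct`, `mass_error` (observed minus
#'   theoretical, Da).
#' @export
annotate_ions <- function(mz, db, tolerance = 0.001,
                          adducts = c("M-H", "M+F")) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a single positive value (Da)", call. = FALSE)
  }
  adducts <- match.arg(adducts, names(.ADDUCT_SHIFTS), several.ok = TRUE)
  stopifnot(!is.null(names(mz)), all(c("compound_id", "mass") %in% names(db)))
  out <- list()
  for (ad in adducts) {
    theo <- db$mass + .ADDUCT_SHIFTS[[ad]]
    # |mz_i - theo_j| <= tol as an outer comparison; db sizes are small
    err <- outer(mz, theo, "-")
    hit <- which(abs(err) <= tolerance, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      out[[ad]] <- data.frame(
        ion_id = names(mz)[hit[, 1L]],
        compound_id = db$compound_id[hit[, 2L]],
        adduct = ad,
        mass_error = err[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ion_id = character(0), compound_id = character(0),
                      adduct = character(0), mass_error = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  ann[order(ann$ion_id, ann$compound_id), , drop = FALSE]
}

#' Normalize an ion-intensity matrix
#'
#' Quantile normalization on the raw intensity scale (removing
#' per-sample loading differences) followed, by default, by a
#' log2(x + 1) transform so that downstream fold changes are mean
#' differences.
#'
#' @param intensities Nonnegative matrix, ions x samples.
#' @param log2_transform Apply log2(x + 1) after normalization
#'   (default TRUE).
#' @return Normalized matrix with the input dimnames.
#' @export
normalize_intensities <- function(intensities, log2_transform = TRUE) {
  if (any(intensities < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  qn <- quantile_normalize(intensities)
  if (log2_transform) log2(qn + 1) else qn
}

#' Correlate ion intensities with donor age
#'
#' Pearson correlation of each ion's (normalized, log-scale) intensity
#' profile with donor age, with Storey q-values computed jointly over
#' all testable ions. Constant ions have no defined correlation: they
#' are reported with NA and excluded from the multiple-testing family
#' with a warning.
#'
#' @param mat Normalized intensity matrix, ions x samples.
#' @param donors Donor table (`sample_id`, `age`, `group`); sample ids
#'   must match the matrix columns exactly.
#' @param lambda Storey pi0 tuning parameter (default 0.5).
#' @return data.frame: `ion_id`, `rho_age`, `p_age`, `q_age`.
#' @export
correlate_with_age <- function(mat, donors, lambda = 0.5) {
  mat <- .match_samples(mat, donors, "intensity matrix")
  constant <- apply(mat, 1L, stats::sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant ion(s) excluded from the ",
            "correlation family", call. = FALSE)
  }
  rho <- p <- rep(NA_real_, nrow(mat))
  for (i in which(!constant)) {
    res <- pearson_correlation(mat[i, ], donors$age, feature = rownames(mat)[i])
    rho[i] <- res$rho
    p[i] <- res$p
  }
  q <- rep(NA_real_, nrow(mat))
  q[!constant] <- storey_qvalues(p[!constant], lambda = lambda)
  data.frame(ion_id = rownames(mat), rho_age = rho, p_age = p, q_age = q,
             stringsAsFactors = FALSE)
}

#' Select age-correlated ions
#'
#' The published rule: |rho| strictly greater than `rho_min` and
#' q strictly below `q_max` (defaults 0.25 and 0.01).
#'
#' @param results Output of [correlate_with_age()].
#' @param rho_min,q_max Significance thresholds.
#' @return data.frame of passing ions with a `direction` column
#'   (`"positive"`/`"negative"`).
#' @export
significant_ions_correlation <- function(results, rho_min = 0.25,
                                         q_max = 0.01) {
  keep <- !is.na(results$rho_age) & abs(results$rho_age) > rho_min &
    results$q_age < q_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$rho_age > 0, "positive", "negative")
  rownames(out) <- NULL
  out
}

#' Old-vs-young differential analysis of ions
#'
#' Per-ion Welch (unpaired, heteroscedastic) t-test of old vs young
#' donors on log2-scale intensities, with the log2 fold change as the
#' group mean difference and Storey q-values over all testable ions.
#'
#' @inheritParams correlate_with_age
#' @return data.frame: `ion_id`, `log2fc` (old minus young), `t`, `p`,
#'   `q`.
#' @export
differential_metabolites <- function(mat, donors, lambda = 0.5) {
  mat <- .match_samples(mat, donors, "intensity matrix")
  old <- donors$group == "old"
  if (sum(old) < 2L || sum(!old) < 2L) {
    stop("each donor group needs at least 2 samples", call. = FALSE)
  }
  n_ion <- nrow(mat)
  fc <- tt <- p <- rep(NA_real_, n_ion)
  degenerate <- logical(n_ion)
  for (i in seq_len(n_ion)) {
    a <- mat[i, old]
    b <- mat[i, !old]
    fc[i] <- log2_fold_change(a, b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      degenerate[i] <- TRUE
      next
    }
    res <- welch_t_test(a, b)
    tt[i] <- res$t
    p[i] <- res$p
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance ion(s) excluded from the ",
            "differential family", call. = FALSE)
  }
  q <- rep(NA_real_, n_ion)
  q[!degenerate] <- storey_qvalues(p[!degenerate], lambda = lambda)
  data.frame(ion_id = rownames(mat), log2fc = fc, t = tt, p = p, q = q,
             stringsAsFactors = FALSE)
}

#' Select differentially abundant ions
#'
#' The published rule: |log2(fold change)| strictly greater than
#' `fc_min` and q strictly below `q_max` (defaults 0.1 and 0.05).
#'
#' @param results Output of [differential_metabolites()].
#' @param fc_min,q_max Significance thresholds.
#' @return data.frame of passing ions with a `direction` column
#'   (`"up"`/`"down"`, old relative to young).
#' @export
significant_ions_differential <- function(results, fc_min = 0.1,
                                          q_max = 0.05) {
  keep <- !is.na(results$q) & abs(results$log2fc) > fc_min &
    results$q < q_max
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
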