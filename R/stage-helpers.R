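# In-memory convenience layer over the pipeline stages, useful for
# simulation studies where file round-trips only add noise.

#' Run normalization, annotation and locality scoring on a dataset bundle
#'
#' Executes the stages a locality analysis needs -- intensity
#' normalization, exact-mass annotation, QC filtering, expression
#' normalization, probe collapsing, ion-to-network mapping, distance
#' computation and the permutation test -- directly on a
#' [generate_dataset()] bundle (or any list with the same fields),
#' without touching the filesystem.
#'
#' @param sim A `metlocal_sim` bundle.
#' @param K Locality permutations (default 1000).
#' @param seed Seed for the permutation stream (default: derived from
#'   the simulation seed).
#' @param d_max Neighborhood radius (default Inf).
#' @return List: `locality` (per-enzyme scores joined with the
#'   transcriptomic age statistics), `gene_differential`,
#'   `annotations`, `hits` (after [filter_locality_hits()] at default
#'   thresholds).
#' @export
run_locality_stage <- function(sim, K = 1000,
                               seed = .substream(sim$config$seed,
                                                 "permutation"),
                               d_max = Inf) {
  donors <- sim$cohort
  norm_metab <- normalize_intensities(sim$ions$intensities)
  norm_metab <- .match_samples(norm_metab, donors, "intensity matrix")
  ann <- annotate_ions(sim$ions$mz, sim$db,
                       tolerance = sim$config$tolerance,
                       adducts = sim$config$adducts)
  expr_qc <- qc_filter_features(sim$expression, sim$flags)
  expr_norm <- quantile_normalize(expr_qc)
  expr_norm <- .match_samples(expr_norm, donors, "expression matrix")
  gene_expr <- collapse_probes_to_genes(expr_norm, sim$gene_map)
  gene_diff <- differential_expression(expr_norm, donors)
  mapped <- map_ions_to_network(ann, norm_metab,
                                igraph::V(sim$network$graph)$name)
  enzymes <- intersect(names(sim$network$enzymes), rownames(gene_expr))
  D <- enzyme_metabolite_distances(sim$network, rownames(mapped$profiles))
  loc <- locality_test(gene_expr[enzymes, , drop = FALSE],
                       mapped$profiles, D[enzymes, , drop = FALSE],
                       K = K, d_max = d_max, seed = seed)
  idx <- match(loc$transcript, gene_diff$feature_id)
  joined <- cbind(loc[, c("transcript", "S", "p_locality", "K",
                          "n_neighbors")],
                  gene_diff[idx, c("rho_age", "p_age", "log2fc", "adj_p")])
  rownames(joined) <- NULL
  list(locality = joined, gene_differential = gene_diff,
       annotations = ann, hits = filter_locality_hits(joined))
}
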