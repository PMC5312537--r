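# End-to-end orchestration: metabolomics -> transcriptomics ->
# enrichment -> network locality -> hit filter, from TSV inputs to TSV
# outputs plus a machine-readable summary.

#' Pipeline configuration
#'
#' Collects all input paths and every analysis threshold. Defaults are
#' the published values: 0.001 Da annotation tolerance; |rho| > 0.25 &
#' q < 0.01 for age-correlated ions; |log2FC| > 0.1 & q < 0.05 for
#' differential ions; |log2FC| > 0.25 & BH p < 0.01 for transcripts;
#' enrichment q < 0.01; locality p < 0.05 with the age filter at
#' p < 0.1 (Spearman) or BH p < 0.1 (differential); K = 10000
#' permutations; Storey lambda 0.5.
#'
#' @param input_dir Directory holding the standard input tables (as
#'   written by [write_dataset()]); individual paths can be overridden.
#' @param out_dir Output directory for stage tables and summary.json.
#' @param donors,ions,expression,db,edges,enzyme_map,pathways_metab,pathways_gene
#'   Paths to the individual input tables.
#' @param tolerance Annotation mass tolerance, Da.
#' @param adducts Adducts considered during annotation.
#' @param rho_min,q_corr Age-correlation significance thresholds.
#' @param fc_min_metab,q_diff Metabolite differential thresholds.
#' @param fc_min_gene,adjp_gene Transcript differential thresholds.
#' @param q_enrich Pathway-enrichment q threshold.
#' @param p_locality,p_age,adjp_hit Locality hit-filter thresholds.
#' @param K Locality permutations.
#' @param lambda Storey pi0 tuning parameter.
#' @param d_max Locality neighborhood radius (Inf = unbounded).
#' @param log2_metab Log2(x+1)-transform normalized intensities.
#' @param seed Base seed; the permutation stream is derived from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            out_dir = file.path(tempdir(), "metlocal_run"),
                            donors = file.path(input_dir, "donors.tsv"),
                            ions = file.path(input_dir, "ions.tsv"),
                            expression = file.path(input_dir, "expression.tsv"),
                            db = file.path(input_dir, "metabolite_db.tsv"),
                            edges = file.path(input_dir, "network_edges.tsv"),
                            enzyme_map = file.path(input_dir, "enzyme_map.tsv"),
                            pathways_metab = file.path(input_dir,
                                                       "pathways_metab.tsv"),
                            pathways_gene = file.path(input_dir,
                                                      "pathways_gene.tsv"),
                            tolerance = 0.001,
                            adducts = c("M-H", "M+F"),
                            rho_min = 0.25, q_corr = 0.01,
                            fc_min_metab = 0.1, q_diff = 0.05,
                            fc_min_gene = 0.25, adjp_gene = 0.01,
                            q_enrich = 0.01,
                            p_locality = 0.05, p_age = 0.1, adjp_hit = 0.1,
                            K = 10000, lambda = 0.5, d_max = Inf,
                            log2_metab = TRUE,
                            seed = 1L) {
  cfg <- list(
    paths = list(donors = donors, ions = ions, expression = expression,
                 db = db, edges = edges, enzyme_map = enzyme_map,
                 pathways_metab = pathways_metab,
                 pathways_gene = pathways_gene),
    out_dir = out_dir,
    tolerance = tolerance, adducts = adducts,
    rho_min = rho_min, q_corr = q_corr,
    fc_min_metab = fc_min_metab, q_diff = q_diff,
    fc_min_gene = fc_min_gene, adjp_gene = adjp_gene,
    q_enrich = q_enrich,
    p_locality = p_locality, p_age = p_age, adjp_hit = adjp_hit,
    K = as.integer(K), lambda = lambda, d_max = d_max,
    log2_metab = log2_metab,
    seed = as.integer(seed)
  )
  for (nm in c("q_corr", "q_diff", "adjp_gene", "q_enrich", "p_locality",
               "p_age", "adjp_hit")) {
    .check_fraction(cfg[[nm]], nm)
  }
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  .check_count(cfg$K, "K")
  structure(cfg, class = "pipeline_config")
}

# Translate compound-level pathway definitions to ion-level ones via
# the annotations: an ion belongs to a pathway when any of its
# candidate compounds does.
.ion_pathways <- function(pathways_metab, annotations) {
  pw <- split(pathways_metab$member_id, pathways_metab$pathway_id)
  lapply(pw, function(cpds) {
    unique(annotations$ion_id[annotations$compound_id %in% cpds])
  })
}

#' Run the integrated pipeline
#'
#' Executes all stages on the configured inputs and writes
#' metab_correlation.tsv, metab_differential.tsv, annotations.tsv,
#' gene_differential.tsv, enrichment_metab.tsv, enrichment_gene.tsv,
#' locality_scores.tsv, locality_hits.tsv and summary.json into the
#' output directory. Reruns with the same config and seed produce
#' identical stage tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  donors <- read_donors(config$paths$donors)

  # -- metabolome stage ----------------------------------------------
  ions <- read_ions(config$paths$ions)
  db <- read_metabolite_db(config$paths$db)
  norm_metab <- normalize_intensities(ions$intensities,
                                      log2_transform = config$log2_metab)
  norm_metab <- .match_samples(norm_metab, donors, "intensity matrix")
  ann <- annotate_ions(ions$mz, db, tolerance = config$tolerance,
                       adducts = config$adducts)
  ml_log("INFO", sprintf("annotation: %d of %d ions annotated",
                         length(unique(ann$ion_id)), length(ions$mz)))
  metab_corr <- correlate_with_age(norm_metab, donors,
                                   lambda = config$lambda)
  sig_corr <- significant_ions_correlation(metab_corr,
                                           rho_min = config$rho_min,
                                           q_max = config$q_corr)
  metab_diff <- differential_metabolites(norm_metab, donors,
                                         lambda = config$lambda)
  sig_diff <- significant_ions_differential(metab_diff,
                                            fc_min = config$fc_min_metab,
                                            q_max = config$q_diff)
  ml_log("INFO", sprintf("metabolome: %d age-correlated, %d differential ions",
                         nrow(sig_corr), nrow(sig_diff)))

  # -- transcriptome stage -------------------------------------------
  ex <- read_expression(config$paths$expression)
  expr_qc <- qc_filter_features(ex$expr, ex$flags)
  expr_norm <- quantile_normalize(expr_qc)
  expr_norm <- .match_samples(expr_norm, donors, "expression matrix")
  gene_diff <- differential_expression(expr_norm, donors)
  sig_genes <- significant_transcripts(gene_diff,
                                       fc_min = config$fc_min_gene,
                                       p_max = config$adjp_gene)
  ml_log("INFO", sprintf("transcriptome: %d of %d features significant",
                         nrow(sig_genes), nrow(gene_diff)))

  # -- pathway enrichment --------------------------------------------
  pathways_metab <- read_pathways(config$paths$pathways_metab)
  pathways_gene <- read_pathways(config$paths$pathways_gene)
  ranked_ions <- sig_diff$ion_id[order(sig_diff$q, sig_diff$p)]
  enr_metab <- enrichment_fdr(
    recursive_enrichment(ranked_ions,
                         .ion_pathways(pathways_metab, ann),
                         background = rownames(norm_metab)),
    lambda = config$lambda, q_max = config$q_enrich
  )
  ranked_genes <- sig_genes$feature_id[order(sig_genes$p)]
  enr_gene <- enrichment_fdr(
    recursive_enrichment(ranked_genes, pathways_gene,
                         background = gene_diff$feature_id),
    lambda = config$lambda, q_max = config$q_enrich
  )

  # -- network locality ----------------------------------------------
  edges <- read_network_edges(config$paths$edges)
  enzyme_map <- read_enzyme_map(config$paths$enzyme_map)
  network <- build_reaction_pair_graph(edges, enzyme_map,
                                       nodes = db$compound_id)
  gene_expr <- collapse_probes_to_genes(expr_norm, ex$gene_map)
  mapped <- map_ions_to_network(ann, norm_metab,
                                compounds = igraph::V(network$graph)$name)
  enzymes <- intersect(names(network$enzymes), rownames(gene_expr))
  if (length(enzymes) == 0L || nrow(mapped$profiles) == 0L) {
    stop("locality analysis needs measured enzymes and mapped metabolites",
         call. = FALSE)
  }
  D <- enzyme_metabolite_distances(network, rownames(mapped$profiles))
  loc <- locality_test(gene_expr[enzymes, , drop = FALSE],
                       mapped$profiles, D[enzymes, , drop = FALSE],
                       K = config$K, d_max = config$d_max,
                       seed = .substream(config$seed, "permutation"))
  idx <- match(loc$transcript, gene_diff$feature_id)
  loc_joined <- cbind(loc[, c("transcript", "S", "p_locality", "K",
                              "n_neighbors")],
                      gene_diff[idx, c("rho_age", "p_age", "log2fc",
                                       "adj_p")])
  hits <- filter_locality_hits(loc_joined,
                               p_locality_max = config$p_locality,
                               p_age_max = config$p_age,
                               adjp_max = config$adjp_hit)
  ml_log("INFO", sprintf("locality: %d significant scores, %d hits",
                         sum(loc_joined$p_locality < config$p_locality,
                             na.rm = TRUE), nrow(hits)))

  # -- outputs --------------------------------------------------------
  out <- config$out_dir
  .write_tsv(metab_corr, file.path(out, "metab_correlation.tsv"))
  .write_tsv(metab_diff, file.path(out, "metab_differential.tsv"))
  .write_tsv(ann, file.path(out, "annotations.tsv"))
  .write_tsv(gene_diff, file.path(out, "gene_differential.tsv"))
  .write_tsv(enr_metab, file.path(out, "enrichment_metab.tsv"))
  .write_tsv(enr_gene, file.path(out, "enrichment_gene.tsv"))
  .write_tsv(loc_joined, file.path(out, "locality_scores.tsv"))
  .write_tsv(hits, file.path(out, "locality_hits.tsv"))
  summary <- list(
    counts = list(
      ions = length(ions$mz),
      ions_annotated = length(unique(ann$ion_id)),
      ions_age_correlated = nrow(sig_corr),
      ions_differential = nrow(sig_diff),
      features = nrow(ex$expr),
      features_after_qc = nrow(expr_qc),
      transcripts_significant = nrow(sig_genes),
      pathways_metab_enriched = sum(enr_metab$significant),
      pathways_gene_enriched = sum(enr_gene$significant),
      enzymes_scored = nrow(loc_joined),
      locality_significant = sum(loc_joined$p_locality < config$p_locality,
                                 na.rm = TRUE),
      locality_hits = nrow(hits)
    ),
    thresholds = config[setdiff(names(config), c("paths", "out_dir"))],
    seed = config$seed,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  summary$thresholds$d_max <- if (is.finite(config$d_max)) config$d_max else "unbounded"
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    donors = donors, annotations = ann,
    metab_correlation = metab_corr, metab_differential = metab_diff,
    significant_ions_correlation = sig_corr,
    significant_ions_differential = sig_diff,
    gene_differential = gene_diff, significant_transcripts = sig_genes,
    enrichment_metab = enr_metab, enrichment_gene = enr_gene,
    locality = loc_joined, hits = hits,
    summary = summary, out_dir = out
  ))
}

#' Summarize a completed pipeline run
#'
#' Reads summary.json and the stage tables from a run directory and
#' prints a human-readable overview: significant ions by direction,
#' transcripts up/down, enriched pathways, and the locality hit table.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list with the parsed summary and hit table.
#' @export
report <- function(run_dir) {
  summary_path <- file.path(run_dir, "summary.json")
  if (!file.exists(summary_path)) {
    stop("not a completed run directory (summary.json missing): ", run_dir,
         call. = FALSE)
  }
  s <- jsonlite::read_json(summary_path, simplifyVector = TRUE)
  cat("metlocal pipeline run:", run_dir, "\n")
  cat(sprintf("  ions detected/annotated:    %d / %d\n",
              s$counts$ions, s$counts$ions_annotated))
  cat(sprintf("  age-correlated ions:        %d\n",
              s$counts$ions_age_correlated))
  cat(sprintf("  differential ions:          %d\n",
              s$counts$ions_differential))
  cat(sprintf("  features (raw/after QC):    %d / %d\n",
              s$counts$features, s$counts$features_after_qc))
  cat(sprintf("  significant transcripts:    %d\n",
              s$counts$transcripts_significant))
  cat(sprintf("  enriched pathways (m/g):    %d / %d\n",
              s$counts$pathways_metab_enriched,
              s$counts$pathways_gene_enriched))
  cat(sprintf("  enzymes scored:             %d\n", s$counts$enzymes_scored))
  cat(sprintf("  locality-significant:       %d\n",
              s$counts$locality_significant))
  cat(sprintf("  locality hits (age filter): %d\n", s$counts$locality_hits))
  hits_path <- file.path(run_dir, "locality_hits.tsv")
  hits <- NULL
  if (file.exists(hits_path)) {
    hits <- .read_tsv(hits_path)
    if (nrow(hits) > 0L) {
      cat("\nTop locality hits:\n")
      print(utils::head(hits[, c("transcript", "S", "p_locality",
                                 "rho_age", "p_age", "log2fc", "adj_p")],
                        10L), row.names = FALSE)
    }
  } else {
    warning("incomplete run: locality_hits.tsv missing", call. = FALSE)
  }
  invisible(list(summary = s, hits = hits))
}
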