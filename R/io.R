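# Plain-TSV readers/writers for every pipeline table. All tables carry
# a header row; matrices use a feature-id first column with sample ids
# as remaining headers.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.matrix_to_df <- function(mat, id_col) {
  out <- data.frame(rownames(mat), mat, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c(id_col, colnames(mat))
  out
}

.df_to_matrix <- function(df, id_col, cols) {
  m <- as.matrix(df[, cols, drop = FALSE])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a synthetic dataset as the pipeline's TSV/JSON inputs
#'
#' Produces donors.tsv, expression.tsv (with per-sample flag columns),
#' ions.tsv, metabolite_db.tsv, network_edges.tsv, enzyme_map.tsv,
#' pathways_metab.tsv, pathways_gene.tsv and ground_truth.json.
#'
#' @param sim A `metlocal_sim` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "metlocal_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(sim$cohort, file.path(dir, "donors.tsv"))
  expr_df <- .matrix_to_df(sim$expression, "feature_id")
  expr_df <- data.frame(feature_id = expr_df$feature_id,
                        gene = unname(sim$gene_map[expr_df$feature_id]),
                        expr_df[, -1, drop = FALSE],
                        stringsAsFactors = FALSE, check.names = FALSE)
  flag_df <- as.data.frame(sim$flags, stringsAsFactors = FALSE)
  names(flag_df) <- paste0("flag_", colnames(sim$flags))
  .write_tsv(cbind(expr_df, flag_df), file.path(dir, "expression.tsv"))
  ion_df <- data.frame(ion_id = names(sim$ions$mz), mz = sim$ions$mz,
                       sim$ions$intensities, stringsAsFactors = FALSE,
                       check.names = FALSE)
  .write_tsv(ion_df, file.path(dir, "ions.tsv"))
  .write_tsv(sim$db, file.path(dir, "metabolite_db.tsv"))
  el <- igraph::as_edgelist(sim$network$graph)
  .write_tsv(data.frame(from = el[, 1], to = el[, 2],
                        stringsAsFactors = FALSE),
             file.path(dir, "network_edges.tsv"))
  .write_tsv(data.frame(gene = names(sim$network$enzymes),
                        compounds = vapply(sim$network$enzymes, paste, "",
                                           collapse = ","),
                        stringsAsFactors = FALSE),
             file.path(dir, "enzyme_map.tsv"))
  .write_tsv(sim$pathways_metab, file.path(dir, "pathways_metab.tsv"))
  .write_tsv(sim$pathways_gene, file.path(dir, "pathways_gene.tsv"))
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a donor table
#' @param path Path to donors.tsv (`sample_id`, `age`, `group`).
#' @return data.frame with `group` as a young/old factor.
#' @export
read_donors <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("sample_id", "age", "group") %in% names(d)))
  d$group <- factor(d$group, levels = c("young", "old"))
  if (anyNA(d$group)) {
    stop("donor groups must be 'young' or 'old'", call. = FALSE)
  }
  d
}

#' Read an expression table with QC flag columns
#' @param path Path to expression.tsv (feature_id, gene, sample
#'   columns, flag_<sample> columns).
#' @return List: `expr` matrix, `flags` matrix, `gene_map` named
#'   vector.
#' @export
read_expression <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("feature_id", "gene") %in% names(d)))
  flag_cols <- grep("^flag_", names(d), value = TRUE)
  sample_cols <- setdiff(names(d), c("feature_id", "gene", flag_cols))
  expr <- .df_to_matrix(d, "feature_id", sample_cols)
  flags <- NULL
  if (length(flag_cols) > 0L) {
    flags <- as.matrix(d[, flag_cols, drop = FALSE])
    dimnames(flags) <- list(d$feature_id, sub("^flag_", "", flag_cols))
    flags <- flags[, sample_cols, drop = FALSE]
  }
  list(expr = expr, flags = flags,
       gene_map = stats::setNames(d$gene, d$feature_id))
}

#' Read an ion-intensity table
#' @param path Path to ions.tsv (ion_id, mz, sample columns).
#' @return List: `mz` named vector, `intensities` matrix.
#' @export
read_ions <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("ion_id", "mz") %in% names(d)))
  sample_cols <- setdiff(names(d), c("ion_id", "mz"))
  list(mz = stats::setNames(d$mz, d$ion_id),
       intensities = .df_to_matrix(d, "ion_id", sample_cols))
}

#' Read a metabolite database table
#' @param path Path to metabolite_db.tsv (compound_id, name, mass,
#'   pathway).
#' @return data.frame.
#' @export
read_metabolite_db <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("compound_id", "mass") %in% names(d)))
  d
}

#' Read a reaction-pair edge list
#' @param path Path to network_edges.tsv (from, to).
#' @return Two-column data.frame.
#' @export
read_network_edges <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("from", "to") %in% names(d)))
  d[, c("from", "to")]
}

#' Read an enzyme-to-metabolite incidence map
#' @param path Path to enzyme_map.tsv (gene, comma-separated
#'   compounds).
#' @return Named list: gene -> character vector of compound ids.
#' @export
read_enzyme_map <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("gene", "compounds") %in% names(d)))
  stats::setNames(strsplit(d$compounds, ","), d$gene)
}

#' Read a pathway definition table
#' @param path Path to a pathways TSV (pathway_id, member_id).
#' @return data.frame.
#' @export
read_pathways <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("pathway_id", "member_id") %in% names(d)))
  d
}
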