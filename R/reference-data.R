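# Published reference statistics bundled with the package.

#' Reference locality statistics for 21 age-associated enzymes
#'
#' The published per-gene results of the locality analysis of human
#' epidermal aging: 21 metabolic enzymes with a significant locality
#' score (p < 0.05) and an age-dependent expression change (gene-age
#' Spearman p < 0.1 or BH-adjusted differential p < 0.1). Columns
#' follow the locality hit-table schema (`gene`, `gene_name`, `S`,
#' `p_locality`, `rho_age`, `p_age`, `log2fc`, `adj_p`) and can be fed
#' directly to [filter_locality_hits()].
#'
#' @return data.frame with 21 rows.
#' @export
reference_locality_hits <- function() {
  path <- system.file("extdata", "reference_locality_hits.tsv",
                      package = "metlocal", mustWork = TRUE)
  .read_tsv(path)
}
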