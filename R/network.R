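# Metabolic reaction-pair network: graph construction, enzyme-metabolite
# network distances, and re-mapping of annotated ions onto network
# metabolites.

#' Build a metabolite reaction-pair graph with enzyme incidence
#'
#' Nodes are metabolites, undirected edges connect substrate-product
#' pairs; duplicate edges are collapsed and self-loops dropped with a
#' warning. Each enzyme maps to its set of incident (distance-1)
#' metabolites; an enzyme referencing an unknown compound is an error
#' listing the offenders.
#'
#' @param edges Two-column matrix or data.frame of compound-id pairs.
#' @param enzyme_map Named list: enzyme/gene id -> character vector of
#'   incident compound ids (each nonempty).
#' @param nodes Optional character vector of all compound ids,
#'   including isolated metabolites absent from the edge list.
#' @return An object of class `"metabolic_network"` with elements
#'   `graph` (igraph) and `enzymes`.
#' @export
build_reaction_pair_graph <- function(edges, enzyme_map, nodes = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L && ncol(edges) != 2L) {
    stop("edges must have two columns", call. = FALSE)
  }
  self <- nrow(edges) > 0L & edges[, 1L] == edges[, 2L]
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from the edge list",
            call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  all_nodes <- unique(c(as.vector(edges), nodes))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = all_nodes
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(names(enzyme_map)) || any(names(enzyme_map) == "")) {
    stop("enzyme_map must be a named list", call. = FALSE)
  }
  if (any(lengths(enzyme_map) == 0L)) {
    stop("every enzyme needs at least one incident metabolite",
         call. = FALSE)
  }
  unknown <- lapply(enzyme_map, setdiff, y = all_nodes)
  bad <- lengths(unknown) > 0L
  if (any(bad)) {
    stop("enzymes reference unknown compounds: ",
         paste(sprintf("%s -> %s", names(unknown)[bad],
                       vapply(unknown[bad], paste, "", collapse = ",")),
               collapse = "; "), call. = FALSE)
  }
  structure(list(graph = g, enzymes = enzyme_map),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("Metabolic reaction-pair network: %d metabolites, %d edges, %d enzymes\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$enzymes)))
  invisible(x)
}

#' Enzyme-metabolite network distance matrix
#'
#' D\[i, m\] = 1 + length of the shortest path from metabolite m to the
#' nearest metabolite incident to enzyme i, so incident metabolites sit
#' at distance 1. Metabolites unreachable from every incident
#' metabolite are Inf (and carry zero weight in the locality score).
#'
#' @param network A `metabolic_network`.
#' @param metabolites Character vector of measured metabolite ids
#'   (must be network nodes).
#' @return Numeric matrix, enzymes x metabolites.
#' @export
enzyme_metabolite_distances <- function(network, metabolites) {
  stopifnot(inherits(network, "metabolic_network"))
  node_names <- igraph::V(network$graph)$name
  unknown <- setdiff(metabolites, node_names)
  if (length(unknown) > 0L) {
    stop("metabolites not in the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  incident_all <- unique(unlist(network$enzymes))
  sp <- igraph::distances(network$graph, v = incident_all, to = metabolites)
  rownames(sp) <- incident_all
  D <- matrix(Inf, nrow = length(network$enzymes),
              ncol = length(metabolites),
              dimnames = list(names(network$enzymes), metabolites))
  for (i in seq_along(network$enzymes)) {
    D[i, ] <- 1 + apply(sp[network$enzymes[[i]], , drop = FALSE], 2L, min)
  }
  D
}

#' Re-map annotated ions to network metabolite profiles
#'
#' Produces one intensity profile per network metabolite from the ion
#' annotations. When several ions annotate one metabolite, the ion with
#' the smallest absolute mass error wins; when one ion annotates
#' several metabolites it contributes to each, flagged ambiguous.
#'
#' @param annotations Output of [annotate_ions()].
#' @param mat Normalized ion-intensity matrix (ions x samples).
#' @param compounds Character vector of network metabolite ids to map
#'   onto.
#' @return List with `profiles` (metabolites x samples matrix, only
#'   metabolites that received an ion) and `mapping` (data.frame:
#'   `compound_id`, `ion_id`, `adduct`, `mass_error`, `ambiguous`).
#' @export
map_ions_to_network <- function(annotations, mat, compounds) {
  ann <- annotations[annotations$compound_id %in% compounds, , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(list(profiles = mat[0, , drop = FALSE],
                mapping = data.frame(compound_id = character(0),
                                     ion_id = character(0),
                                     adduct = character(0),
                                     mass_error = numeric(0),
                                     ambiguous = logical(0),
                                     stringsAsFactors = FALSE)))
  }
  picked <- do.call(rbind, lapply(split(ann, ann$compound_id), function(d) {
    d[which.min(abs(d$mass_error)), , drop = FALSE]
  }))
  pair <- unique(ann[, c("ion_id", "compound_id")])
  multi <- names(which(table(pair$ion_id) > 1L))
  picked$ambiguous <- picked$ion_id %in% multi
  picked <- picked[, c("compound_id", "ion_id", "adduct", "mass_error",
                       "ambiguous")]
  rownames(picked) <- NULL
  profiles <- mat[picked$ion_id, , drop = FALSE]
  rownames(profiles) <- picked$compound_id
  list(profiles = profiles, mapping = picked)
}
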