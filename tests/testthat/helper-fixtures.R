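# Shared fixtures and small independent oracles used across tests.

# All permutations of 1..n as rows (n! x n); used for exhaustive
# permutation-null enumeration on tiny metabolite sets.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Independent locality-score evaluation: direct transcription of the
# weighted-mean formula, no shared code with the package internals.
oracle_locality_score <- function(C, pC, D, d_max = Inf) {
  num <- den <- 0
  for (m in seq_along(C)) {
    if (!is.finite(D[m]) || D[m] > d_max) next
    w <- D[m]^-2 * (1 - pC[m])
    num <- num + w * abs(C[m])
    den <- den + w
  }
  num / den
}

# Independent upper-tail hypergeometric probability built from choose():
# P(X >= k) for X ~ Hypergeom(ptw_all of total_all, total_hits drawn).
oracle_hyper_tail <- function(k, total_all, ptw_all, total_hits) {
  i <- k:min(ptw_all, total_hits)
  sum(choose(ptw_all, i) * choose(total_all - ptw_all, total_hits - i)) /
    choose(total_all, total_hits)
}

# A three-node path network A-B-C with two enzymes.
path_network <- function() {
  build_reaction_pair_graph(
    edges = rbind(c("A", "B"), c("B", "C")),
    enzyme_map = list(E_A = "A", E_AB = c("A", "B"))
  )
}

# Small synthetic configuration for fast end-to-end tests.
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_young = 8, n_old = 8, n_ions = 60, n_genes = 50,
         n_metabolites = 30, n_enzymes = 20, n_planted_enzymes = 4,
         seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}
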