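# Reaction-pair graph, enzyme-metabolite distances, ion-to-network
# mapping, locality scoring, permutation null and the hit filter.

test_that("graph construction collapses duplicates and validates enzymes", {
  net <- build_reaction_pair_graph(rbind(c("A", "B"), c("B", "A")),
                                   list(E1 = "A"))
  expect_equal(igraph::ecount(net$graph), 1)
  expect_warning(
    net2 <- build_reaction_pair_graph(rbind(c("A", "A"), c("A", "B")),
                                      list(E1 = "A")),
    "self-loop")
  expect_equal(igraph::ecount(net2$graph), 1)
  expect_error(build_reaction_pair_graph(rbind(c("A", "B")),
                                         list(E1 = c("A", "Z"))), "Z")
  expect_error(build_reaction_pair_graph(rbind(c("A", "B")),
                                         list(E1 = character(0))),
               "at least one")
})

test_that("enzyme-metabolite distances are 1 + shortest path to incidence", {
  net <- path_network()
  D <- enzyme_metabolite_distances(net, c("A", "B", "C"))
  expect_equal(unname(D["E_A", ]), c(1, 2, 3))
  expect_equal(unname(D["E_AB", ]), c(1, 1, 2))
  # disconnected metabolites are unreachable
  net2 <- build_reaction_pair_graph(rbind(c("A", "B")), list(E1 = "A"),
                                    nodes = c("A", "B", "X"))
  D2 <- enzyme_metabolite_distances(net2, c("A", "X"))
  expect_equal(unname(D2["E1", "A"]), 1)
  expect_true(is.infinite(D2["E1", "X"]))
})

test_that("ion-to-network mapping picks the smallest mass error", {
  ann <- data.frame(
    ion_id = c("i1", "i2", "i3", "i3"),
    compound_id = c("A", "A", "B", "C"),
    adduct = "M-H",
    mass_error = c(0.0007, 0.0002, 0.0001, 0.0004)
  )
  mat <- matrix(1:8, nrow = 4,
                dimnames = list(c("i1", "i2", "i3", "i4"), c("S1", "S2")))
  out <- map_ions_to_network(ann, mat, compounds = c("A", "B", "C"))
  mp <- out$mapping
  expect_equal(mp$ion_id[mp$compound_id == "A"], "i2")
  # one ion feeding two metabolites: both profiles identical, flagged
  expect_true(all(mp$ambiguous[mp$compound_id %in% c("B", "C")]))
  expect_false(mp$ambiguous[mp$compound_id == "A"])
  expect_equal(unname(out$profiles["B", ]), unname(out$profiles["C", ]))
})

test_that("locality score evaluates the weighted-mean formula", {
  # single neighbor: weights cancel, S = |C|
  for (C in c(0.5, -0.31, 0.99)) {
    expect_equal(locality_score(C, 0.2, 3), abs(C), tolerance = 1e-12)
  }
  # all-zero correlations give S = 0
  expect_equal(locality_score(c(0, 0, 0), c(0.1, 0.5, 0.9), c(1, 2, 3)), 0)
  # worked two-neighbor case
  expect_equal(locality_score(c(0.8, 0.2), c(0.01, 0.5), c(1, 2)),
               (1 * 0.99 * 0.8 + 0.25 * 0.5 * 0.2) / (0.99 + 0.125),
               tolerance = 1e-12)
  # unreachable metabolites carry no weight
  expect_equal(locality_score(c(0.8, 0.9), c(0.01, 0.01), c(1, Inf)), 0.8)
  # d_max prunes the neighborhood
  expect_equal(locality_score(c(0.8, 0.2), c(0.01, 0.5), c(1, 5),
                              d_max = 2), 0.8)
  expect_error(locality_score(0.5, 0.5, Inf), "empty neighborhood")
  # agreement with an independent transcription of the formula
  set.seed(41)
  for (i in 1:10) {
    C <- runif(6, -1, 1); pC <- runif(6); D <- sample(1:5, 6, TRUE)
    expect_equal(locality_score(C, pC, D), oracle_locality_score(C, pC, D),
                 tolerance = 1e-12)
  }
})

test_that("locality scores are invariant to metabolite relabeling", {
  set.seed(42)
  expr <- matrix(rnorm(3 * 20), nrow = 3,
                 dimnames = list(paste0("E", 1:3), paste0("S", 1:20)))
  metab <- matrix(rnorm(6 * 20), nrow = 6,
                  dimnames = list(paste0("M", 1:6), paste0("S", 1:20)))
  D <- matrix(sample(1:4, 18, TRUE), nrow = 3,
              dimnames = list(rownames(expr), rownames(metab)))
  s1 <- locality_test(expr, metab, D, K = 10, seed = 1)
  perm <- sample(6)
  s2 <- locality_test(expr, metab[perm, ], D[, perm], K = 10, seed = 1)
  expect_equal(s1$S, s2$S, tolerance = 1e-12)
})

test_that("identical distances make every permutation score equal (p = 1)", {
  set.seed(43)
  expr <- matrix(rnorm(2 * 15), nrow = 2,
                 dimnames = list(c("E1", "E2"), paste0("S", 1:15)))
  metab <- matrix(rnorm(4 * 15), nrow = 4,
                  dimnames = list(paste0("M", 1:4), paste0("S", 1:15)))
  D <- matrix(2, nrow = 2, ncol = 4,
              dimnames = list(rownames(expr), rownames(metab)))
  res <- locality_test(expr, metab, D, K = 50, seed = 9)
  expect_equal(res$p_locality, c(1, 1))
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(44)
  n <- 24
  expr <- matrix(rnorm(n), nrow = 1,
                 dimnames = list("E1", paste0("S", 1:n)))
  metab <- matrix(rnorm(4 * n), nrow = 4,
                  dimnames = list(paste0("M", 1:4), paste0("S", 1:n)))
  metab[1, ] <- metab[1, ] + 1.5 * expr[1, ]
  D <- matrix(c(1, 2, 3, 4), nrow = 1,
              dimnames = list("E1", rownames(metab)))
  # independent oracle: spearman via cor.test, exhaustive 4! permutations
  C <- pC <- numeric(4)
  for (m in 1:4) {
    ct <- suppressWarnings(cor.test(expr[1, ], metab[m, ],
                                    method = "spearman", exact = FALSE))
    C[m] <- unname(ct$estimate)
    pC[m] <- ct$p.value
  }
  S <- oracle_locality_score(C, pC, as.numeric(D))
  perms <- all_permutations(4)
  S_rand <- apply(perms, 1, function(pp) {
    oracle_locality_score(C, pC, as.numeric(D)[pp])
  })
  p_exh <- mean(S_rand >= S)
  res <- locality_test(expr, metab, D, K = 4000, seed = 3)
  expect_equal(res$S, S, tolerance = 1e-10)
  se <- sqrt(p_exh * (1 - p_exh) / 4000)
  expect_lt(abs(res$p_locality - p_exh), 3 * se + 1e-9)
})

test_that("hit filter implements the locality and age-dependence gates", {
  ref <- reference_locality_hits()
  # a reported top hit passes via both branches
  aldh <- ref[ref$gene == "ALDH4A1", ]
  expect_equal(nrow(filter_locality_hits(aldh)), 1L)
  # a reported hit passing only through the differential branch
  aga <- ref[ref$gene == "AGA", ]
  expect_false(aga$p_age < 0.1)
  expect_true(aga$adj_p < 0.1)
  expect_equal(nrow(filter_locality_hits(aga)), 1L)
  # failing the locality gate excludes regardless of age evidence
  fake <- data.frame(p_locality = 0.06, p_age = 0.01, adj_p = 0.001)
  expect_equal(nrow(filter_locality_hits(fake)), 0L)
  # failing both age branches excludes despite locality significance
  fake2 <- data.frame(p_locality = 0.001, p_age = 0.5, adj_p = 0.5)
  expect_equal(nrow(filter_locality_hits(fake2)), 0L)
  # output ordered by locality p-value
  out <- filter_locality_hits(ref)
  expect_false(is.unsorted(out$p_locality))
})
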