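# Synthetic-data generator: cohort structure, toy network, matched
# omics with planted effects, QC artifact spiking.

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(age_range_young = c(20, 60)), "disjoint")
  expect_error(sim_config(n_planted_enzymes = 500), "n_planted")
  expect_error(sim_config(n_enzymes = 1000, n_genes = 10), "n_enzymes")
  expect_error(sim_config(n_ions = 10, n_metabolites = 100), "n_ions")
  expect_error(sim_config(coupling_strength = 1.2), "coupling")
})

test_that("cohorts have the right sizes, age ranges, and are deterministic", {
  cfg <- sim_config(n_young = 2, n_old = 2, seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 4L)
  expect_equal(as.vector(table(co$group)), c(2L, 2L))
  for (s in 1:5) {
    co <- generate_cohort(sim_config(seed = s))
    expect_true(all(co$age[co$group == "young"] >= 20 &
                      co$age[co$group == "young"] <= 25))
    expect_true(all(co$age[co$group == "old"] >= 55 &
                      co$age[co$group == "old"] <= 66))
  }
  expect_identical(generate_cohort(sim_config(seed = 11)),
                   generate_cohort(sim_config(seed = 11)))
})

test_that("toy network is connected with unambiguous compound masses", {
  for (s in 1:3) {
    net <- generate_toy_network(small_config(seed = s))
    expect_true(igraph::is_connected(net$network$graph))
    expect_true(all(lengths(net$network$enzymes) %in% 1:3))
    gaps <- diff(sort(net$db$mass))
    expect_true(all(gaps > 3 * 0.001))
    expect_true(all(net$db$mass > 80 & net$db$mass < 900))
  }
})

test_that("matched omics share sample ids and carry the planted structure", {
  cfg <- small_config(seed = 5)
  co <- generate_cohort(cfg)
  net <- generate_toy_network(cfg)
  om <- generate_matched_omics(co, net$network, net$db, cfg)
  expect_identical(colnames(om$expression), co$sample_id)
  expect_identical(colnames(om$ions$intensities), co$sample_id)
  gt <- om$ground_truth
  expect_length(gt$planted_enzymes, cfg$n_planted_enzymes)
  # affected metabolites sit at network distance 1 from their enzyme
  for (g in names(gt$affected_metabolites)) {
    expect_true(all(gt$affected_metabolites[[g]] %in%
                      net$network$enzymes[[g]]))
  }
  # ion m/z are [M-H]- masses within the simulated mass error
  nm <- nrow(net$db)
  expect_true(all(abs(om$ions$mz[seq_len(nm)] -
                        (net$db$mass - 1.007276)) <= 0.0005 + 1e-12))
  # determinism of the whole bundle
  om2 <- generate_matched_omics(co, net$network, net$db, cfg)
  expect_identical(om, om2)
})

test_that("planted enzymes correlate with their distance-1 metabolites", {
  # Monte-Carlo over seeds: coupling 0.9 / noise 0.1 must make the
  # planted-neighbor |spearman| clearly exceed random pairs
  set.seed(77)
  planted_cor <- random_cor <- numeric(0)
  for (s in 1:20) {
    cfg <- small_config(seed = s, coupling_strength = 0.9, noise_sd = 0.1)
    co <- generate_cohort(cfg)
    net <- generate_toy_network(cfg)
    om <- generate_matched_omics(co, net$network, net$db, cfg)
    lg <- log2(om$ions$intensities)
    gt <- om$ground_truth
    for (g in names(gt$affected_metabolites)) {
      idx <- match(gt$affected_metabolites[[g]], net$db$compound_id)
      for (i in idx) {
        planted_cor <- c(planted_cor,
                         abs(cor(om$expression[g, ], lg[i, ],
                                 method = "spearman")))
      }
      far <- sample(setdiff(seq_len(nrow(net$db)),
                            match(unlist(gt$affected_metabolites),
                                  net$db$compound_id)), 2)
      for (i in far) {
        random_cor <- c(random_cor,
                        abs(cor(om$expression[g, ], lg[i, ],
                                method = "spearman")))
      }
    }
  }
  expect_gt(mean(planted_cor), mean(random_cor))
  expect_gt(mean(planted_cor), 0.6)
})

test_that("null constructions carry no signal knobs", {
  cfg <- small_config(seed = 2, coupling_strength = 0,
                      effect_size_gene = 0, n_planted_enzymes = 0)
  om <- generate_matched_omics(generate_cohort(cfg),
                               generate_toy_network(cfg)$network,
                               generate_toy_network(cfg)$db, cfg)
  expect_length(om$ground_truth$planted_enzymes, 0L)
  expect_length(om$ground_truth$affected_metabolites, 0L)
})

test_that("artifact spiking flags >= 50% of samples and respects exclusions", {
  cfg <- small_config(seed = 4, frac_saturated = 0.1, frac_background = 0.1)
  sim <- generate_dataset(cfg)
  flagged <- rownames(sim$flags)[rowSums(sim$flags != "ok") > 0]
  expect_gt(length(flagged), 0L)
  frac <- rowMeans(sim$flags[flagged, , drop = FALSE] != "ok")
  expect_true(all(frac >= 0.5))
  expect_false(any(flagged %in% sim$ground_truth$planted_enzymes))
  # zero fractions mean zero flags
  cfg0 <- small_config(seed = 4, frac_saturated = 0, frac_background = 0)
  expect_true(all(spike_artifacts(sim$expression, cfg0) == "ok"))
  # determinism
  expect_identical(spike_artifacts(sim$expression, cfg),
                   spike_artifacts(sim$expression, cfg))
})

test_that("the full dataset bundle is a pure function of the config", {
  a <- generate_dataset(small_config(seed = 9))
  b <- generate_dataset(small_config(seed = 9))
  expect_identical(a$expression, b$expression)
  expect_identical(a$ions, b$ions)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_dataset(small_config(seed = 10))
  expect_false(identical(a$expression, c2$expression))
})
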