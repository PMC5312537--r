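# Synthetic matched-omics generator: donor cohorts, a toy metabolic
# reaction-pair network with compound masses, and expression/intensity
# matrices with planted, network-localized age effects. Every downstream
# stage of the pipeline is testable against the recorded ground truth.

#' Simulation configuration
#'
#' Defaults emulate the matched study design: two all-female age groups
#' (young 20-25 y, old 55-66 y) with 23 donors each measured on both
#' omics, log2-scale intensities, and a subset of enzyme-coding genes
#' carrying a group effect that propagates to their distance-1
#' metabolites.
#'
#' @param n_young,n_old Donor counts per group (default 23 each, the
#'   matched-cohort size).
#' @param age_range_young,age_range_old Inclusive integer age ranges in
#'   years; must be disjoint with young below old.
#' @param n_ions Total ions measured; the first `n_metabolites` ions are
#'   \[M-H\]- ions of the database compounds, the remainder are
#'   unannotatable noise ions.
#' @param n_genes Expression features (1:1 probe-gene by construction).
#' @param n_metabolites Compounds in the toy network/database.
#' @param n_enzymes Enzyme-coding genes wired into the network (the
#'   first `n_enzymes` gene ids); must not exceed `n_genes`.
#' @param n_planted_enzymes Enzymes given a true age effect whose
#'   distance-1 metabolites co-vary with their expression.
#' @param effect_size_gene Group contrast for planted enzymes, log2
#'   units (default 1).
#' @param coupling_strength Target correlation magnitude between a
#'   planted enzyme's expression and its distance-1 metabolites, in
#'   \[0, 1\] (default 0.8).
#' @param noise_sd Per-gene Gaussian noise, log2 units (default 0.2).
#' @param frac_saturated,frac_background Fractions of features spiked
#'   with saturation / background QC flags in >= 50% of samples.
#' @param adducts Adduct set generated for ions: `"M-H"` (default) or
#'   `c("M-H", "M+F")`.
#' @param tolerance Annotation mass tolerance in Da; compound masses are
#'   kept more than 3x this apart so annotation is unambiguous.
#' @param seed Base RNG seed; all generator randomness derives from it
#'   via named substreams.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_young = 23, n_old = 23,
                       age_range_young = c(20, 25),
                       age_range_old = c(55, 66),
                       n_ions = 300, n_genes = 400,
                       n_metabolites = 150, n_enzymes = 200,
                       n_planted_enzymes = 20,
                       effect_size_gene = 1,
                       coupling_strength = 0.8,
                       noise_sd = 0.2,
                       frac_saturated = 0.02,
                       frac_background = 0.03,
                       adducts = "M-H",
                       tolerance = 0.001,
                       seed = 1L) {
  for (nm in c("n_young", "n_old", "n_ions", "n_genes", "n_metabolites",
               "n_enzymes")) {
    .check_count(get(nm), nm)
  }
  .check_count(n_planted_enzymes, "n_planted_enzymes", min = 0L)
  .check_fraction(frac_saturated, "frac_saturated")
  .check_fraction(frac_background, "frac_background")
  .check_fraction(coupling_strength, "coupling_strength")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (n_metabolites < 3L) stop("need at least 3 metabolites", call. = FALSE)
  if (n_enzymes > n_genes) {
    stop("n_enzymes cannot exceed n_genes", call. = FALSE)
  }
  if (n_planted_enzymes > n_enzymes) {
    stop("n_planted_enzymes cannot exceed n_enzymes", call. = FALSE)
  }
  if (n_ions < n_metabolites) {
    stop("n_ions must be at least n_metabolites (one ion per compound)",
         call. = FALSE)
  }
  if (length(age_range_young) != 2L || length(age_range_old) != 2L ||
      diff(age_range_young) < 0 || diff(age_range_old) < 0) {
    stop("age ranges must be increasing length-2 vectors", call. = FALSE)
  }
  if (age_range_young[2] >= age_range_old[1]) {
    stop("age ranges must be disjoint with young < old", call. = FALSE)
  }
  if (!all(adducts %in% names(.ADDUCT_SHIFTS))) {
    stop("adducts must be among: ",
         paste(names(.ADDUCT_SHIFTS), collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    age_range_young = as.integer(age_range_young),
    age_range_old = as.integer(age_range_old),
    n_ions = as.integer(n_ions), n_genes = as.integer(n_genes),
    n_metabolites = as.integer(n_metabolites),
    n_enzymes = as.integer(n_enzymes),
    n_planted_enzymes = as.integer(n_planted_enzymes),
    effect_size_gene = effect_size_gene,
    coupling_strength = coupling_strength,
    noise_sd = noise_sd,
    frac_saturated = frac_saturated, frac_background = frac_background,
    adducts = adducts, tolerance = tolerance,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a donor cohort table
#'
#' One row per donor with integer ages drawn uniformly within the
#' group's range; young donors first. Deterministic for a fixed config.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `sample_id`, `age`, `group` (factor,
#'   levels young/old).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_young + config$n_old
  .with_seed(.substream(config$seed, "cohort"), {
    age_y <- sample(seq(config$age_range_young[1], config$age_range_young[2]),
                    config$n_young, replace = TRUE)
    age_o <- sample(seq(config$age_range_old[1], config$age_range_old[2]),
                    config$n_old, replace = TRUE)
    data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      age = c(age_y, age_o),
      group = factor(rep(c("young", "old"), c(config$n_young, config$n_old)),
                     levels = c("young", "old")),
      stringsAsFactors = FALSE
    )
  })
}

# Draw n distinct monoisotopic masses in [80, 900] Da on a 0.005-Da grid,
# resampling until every pairwise distance between all generated adduct
# masses exceeds 3x the annotation tolerance.
.draw_masses <- function(n, adducts, tolerance, max_tries = 50L) {
  grid <- seq(80, 900, by = 0.005)
  if (n > length(grid)) {
    stop("cannot draw ", n, " unique masses with the required separation",
         call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    masses <- sort(sample(grid, n))
    adduct_mz <- sort(as.vector(outer(masses, .ADDUCT_SHIFTS[adducts], "+")))
    if (min(diff(adduct_mz)) > 3 * tolerance) return(masses)
  }
  stop("could not achieve unambiguous mass separation at tolerance ",
       tolerance, call. = FALSE)
}

#' Generate a toy metabolic network and compound database
#'
#' Builds a connected metabolite graph (random spanning tree plus ~20%
#' extra edges), assigns each enzyme-coding gene 1-3 incident metabolites
#' (its reaction substrates/products), gives every compound a unique
#' monoisotopic mass separated by more than 3x the annotation tolerance,
#' and partitions metabolites and enzymes into pathway blocks.
#'
#' @param config A [sim_config()].
#' @return List with elements `network` (a `metabolic_network`), `db`
#'   (compound table: compound_id, name, mass, pathway),
#'   `pathways_metab` and `pathways_gene` (pathway_id / member_id
#'   tables).
#' @export
generate_toy_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nm <- config$n_metabolites
  compounds <- sprintf("C%04d", seq_len(nm))
  .with_seed(.substream(config$seed, "network"), {
    masses <- .draw_masses(nm, config$adducts, config$tolerance)
    # spanning tree: each node joins an earlier one; extra edges close loops
    parent <- vapply(2:nm, function(i) sample.int(i - 1L, 1L), integer(1))
    edges <- cbind(compounds[parent], compounds[2:nm])
    n_extra <- max(1L, round(0.2 * nm))
    extra <- t(replicate(n_extra, sample(compounds, 2L)))
    edges <- rbind(edges, extra)
    enzymes <- sprintf("G%04d", seq_len(config$n_enzymes))
    incident <- lapply(seq_len(config$n_enzymes), function(i) {
      sample(compounds, sample.int(3L, 1L))
    })
    names(incident) <- enzymes
    block <- function(ids, size, prefix) {
      data.frame(pathway_id = sprintf("%s%02d", prefix,
                                      ceiling(seq_along(ids) / size)),
                 member_id = ids, stringsAsFactors = FALSE)
    }
    pathways_metab <- block(sample(compounds), 15L, "mpw")
    pathways_gene <- block(sample(enzymes), 20L, "gpw")
    db <- data.frame(
      compound_id = compounds,
      name = sprintf("metabolite_%04d", seq_len(nm)),
      mass = masses,
      pathway = pathways_metab$pathway_id[match(compounds,
                                                pathways_metab$member_id)],
      stringsAsFactors = FALSE
    )
    network <- build_reaction_pair_graph(edges, incident, nodes = compounds)
    list(network = network, db = db,
         pathways_metab = pathways_metab[order(pathways_metab$pathway_id,
                                               pathways_metab$member_id), ],
         pathways_gene = pathways_gene[order(pathways_gene$pathway_id,
                                             pathways_gene$member_id), ])
  })
}

#' Generate matched expression and ion-intensity matrices
#'
#' Gene expression is baseline + group effect (planted enzymes only) +
#' Gaussian noise on log2 scale, plus a per-sample array offset that
#' quantile normalization removes. For each planted enzyme, its
#' distance-1 metabolites receive a standardized component of the
#' enzyme's expression scaled by `coupling_strength` (sign randomized
#' per metabolite and recorded); all other metabolites are independent
#' noise. Ion m/z values are \[M-H\]- masses of their metabolites plus a
#' uniform mass error within +/-0.0005 Da; surplus ions are unannotatable
#' noise.
#'
#' @param cohort Output of [generate_cohort()].
#' @param network The `metabolic_network` from [generate_toy_network()].
#' @param db The compound table from [generate_toy_network()].
#' @param config A [sim_config()].
#' @return List with `expression` (genes x samples, log2), `ions`
#'   (list: `mz` named vector, `intensities` raw-scale matrix), and
#'   `ground_truth` (planted enzymes, affected metabolites, signs).
#' @export
generate_matched_omics <- function(cohort, network, db, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(network, "metabolic_network"))
  n <- nrow(cohort)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  enzymes <- names(network$enzymes)
  if (config$n_planted_enzymes > length(enzymes)) {
    stop("planted enzyme count exceeds the enzyme set", call. = FALSE)
  }
  old <- cohort$group == "old"
  .with_seed(.substream(config$seed, "omics"), {
    planted <- sort(sample(enzymes, config$n_planted_enzymes))
    effect_dir <- stats::setNames(sample(c(-1, 1), length(planted),
                                         replace = TRUE), planted)
    baseline_g <- stats::runif(config$n_genes, 6, 12)
    expr <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, cohort$sample_id))
    expr <- expr + baseline_g
    for (g in planted) {
      expr[g, old] <- expr[g, old] + config$effect_size_gene * effect_dir[[g]]
    }
    # metabolite log2 abundances; claimed distance-1 metabolites track
    # their enzyme's standardized expression at the target correlation
    met_base <- stats::runif(nrow(db), 10, 18)
    names(met_base) <- db$compound_id
    latent <- matrix(stats::rnorm(nrow(db) * n), nrow = nrow(db),
                     dimnames = list(db$compound_id, cohort$sample_id))
    affected <- list()
    signs <- list()
    claimed <- character(0)
    cc <- config$coupling_strength
    for (g in planted) {
      mets <- setdiff(network$enzymes[[g]], claimed)
      if (length(mets) == 0L) next
      z <- as.numeric(scale(expr[g, ]))
      s <- sample(c(-1, 1), length(mets), replace = TRUE)
      for (j in seq_along(mets)) {
        latent[mets[j], ] <- s[j] * cc * z +
          sqrt(1 - cc^2) * stats::rnorm(n)
      }
      affected[[g]] <- mets
      signs[[g]] <- stats::setNames(s, mets)
      claimed <- c(claimed, mets)
    }
    met_log2 <- met_base + 0.5 * latent
    # ions: one [M-H]- ion per compound, plus unannotatable noise ions;
    # a per-sample loading offset mimics tissue-amount differences that
    # quantile normalization removes
    n_noise <- config$n_ions - nrow(db)
    sample_off_m <- stats::rnorm(n, sd = 0.3)
    sample_off_e <- stats::rnorm(n, sd = 0.3)
    expr <- sweep(expr, 2L, sample_off_e, "+")
    ion_ids <- sprintf("I%04d", seq_len(config$n_ions))
    mz <- numeric(config$n_ions)
    log2_int <- matrix(0, nrow = config$n_ions, ncol = n,
                       dimnames = list(ion_ids, cohort$sample_id))
    mz[seq_len(nrow(db))] <- db$mass + .ADDUCT_SHIFTS[["M-H"]] +
      stats::runif(nrow(db), -0.0005, 0.0005)
    log2_int[seq_len(nrow(db)), ] <- met_log2
    if (n_noise > 0L) {
      noise_mz <- .draw_noise_mz(n_noise, db$mass, config$adducts,
                                 config$tolerance)
      mz[nrow(db) + seq_len(n_noise)] <- noise_mz
      log2_int[nrow(db) + seq_len(n_noise), ] <-
        stats::runif(n_noise, 10, 18) +
        matrix(stats::rnorm(n_noise * n, sd = 0.5), nrow = n_noise)
    }
    log2_int <- sweep(log2_int, 2L, sample_off_m, "+")
    names(mz) <- ion_ids
    list(
      expression = expr,
      ions = list(mz = mz, intensities = 2^log2_int),
      ground_truth = list(planted_enzymes = planted,
                          effect_direction = effect_dir,
                          affected_metabolites = affected,
                          coupling_sign = signs)
    )
  })
}

# m/z values for noise ions, kept > 3x tolerance away from every adduct
# mass of every database compound so they stay unannotated.
.draw_noise_mz <- function(n_noise, db_masses, adducts, tolerance) {
  adduct_mz <- sort(as.vector(outer(db_masses, .ADDUCT_SHIFTS[adducts], "+")))
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n_noise && tries < 50L) {
    cand <- stats::runif(2L * n_noise, 79, 899)
    idx <- findInterval(cand, adduct_mz)
    lo <- c(-Inf, adduct_mz)[idx + 1L]
    hi <- c(adduct_mz, Inf)[idx + 1L]
    keep <- pmin(cand - lo, hi - cand) > 3 * tolerance
    out <- c(out, cand[keep])
    tries <- tries + 1L
  }
  if (length(out) < n_noise) {
    stop("could not place noise ions away from adduct masses", call. = FALSE)
  }
  out[seq_len(n_noise)]
}

#' Spike saturation/background QC flags into an expression matrix
#'
#' Randomly chosen features receive `"saturated"` or `"background"`
#' flags in a randomly chosen >= 50% of samples, so the downstream QC
#' filter (removal at >= 50% flagged) removes exactly the spiked
#' features.
#'
#' @param expression Expression matrix (features x samples).
#' @param config A [sim_config()] supplying `frac_saturated`,
#'   `frac_background` and the seed.
#' @param exclude Feature ids never to spike (e.g. planted enzymes).
#' @return Character matrix of flags (`"ok"`, `"saturated"`,
#'   `"background"`) with the expression matrix's dimnames.
#' @export
spike_artifacts <- function(expression, config, exclude = NULL) {
  stopifnot(inherits(config, "sim_config"))
  flags <- matrix("ok", nrow = nrow(expression), ncol = ncol(expression),
                  dimnames = dimnames(expression))
  n_feat <- nrow(expression)
  ns <- ncol(expression)
  pool <- setdiff(rownames(expression), exclude)
  n_sat <- round(config$frac_saturated * n_feat)
  n_bg <- round(config$frac_background * n_feat)
  if (n_sat + n_bg == 0L) return(flags)
  if (n_sat + n_bg > length(pool)) {
    stop("not enough spikeable features for the requested fractions",
         call. = FALSE)
  }
  .with_seed(.substream(config$seed, "artifacts"), {
    chosen <- sample(pool, n_sat + n_bg)
    lab <- rep(c("saturated", "background"), c(n_sat, n_bg))
    for (i in seq_along(chosen)) {
      k <- sample(seq(ceiling(ns / 2), ns), 1L)
      flags[chosen[i], sample.int(ns, k)] <- lab[i]
    }
    flags
  })
}

#' Generate a complete synthetic matched-omics dataset
#'
#' Convenience wrapper running [generate_cohort()],
#' [generate_toy_network()], [generate_matched_omics()] and
#' [spike_artifacts()] (artifacts are spiked only on non-planted
#' features so QC removal never silently deletes the planted signal).
#'
#' @param config A [sim_config()].
#' @return A list of class `"metlocal_sim"` bundling config, cohort,
#'   network, compound database, pathway tables, expression + flags,
#'   ions, and ground truth.
#' @export
generate_dataset <- function(config = sim_config()) {
  cohort <- generate_cohort(config)
  net <- generate_toy_network(config)
  om <- generate_matched_omics(cohort, net$network, net$db, config)
  flags <- spike_artifacts(om$expression, config,
                           exclude = om$ground_truth$planted_enzymes)
  structure(list(
    config = config,
    cohort = cohort,
    network = net$network,
    db = net$db,
    pathways_metab = net$pathways_metab,
    pathways_gene = net$pathways_gene,
    expression = om$expression,
    flags = flags,
    gene_map = stats::setNames(rownames(om$expression),
                               rownames(om$expression)),
    ions = om$ions,
    ground_truth = om$ground_truth
  ), class = "metlocal_sim")
}

#' @export
print.metlocal_sim <- function(x, ...) {
  cat("Synthetic matched-omics dataset\n")
  cat(sprintf("  donors:      %d young / %d old\n",
              sum(x$cohort$group == "young"), sum(x$cohort$group == "old")))
  cat(sprintf("  ions:        %d (%d compound-derived)\n",
              length(x$ions$mz), nrow(x$db)))
  cat(sprintf("  genes:       %d (%d enzymes, %d planted)\n",
              nrow(x$expression), length(x$network$enzymes),
              length(x$ground_truth$planted_enzymes)))
  invisible(x)
}
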