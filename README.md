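# metlocal

Integrative analysis of matched metabolomics and transcriptomics cohorts,
built around a network-based **locality score** that identifies metabolic
enzymes whose age- (or condition-) dependent expression change leaves a
functional footprint on the metabolites surrounding them in the metabolic
network.

The motivating setting is molecular aging of human epidermis: untargeted
negative-mode flow-injection metabolomics and microarray transcriptomics
measured on the same donors from two age groups (young, 20–25 y; old,
55–66 y). Both individual omics show only mild age effects, so the
interesting signal is *concordance*: an enzyme whose transcript change is
accompanied by correlated changes in its proximal substrates and products.

## The method

For a metabolic enzyme-coding transcript *t<sub>i</sub>* and metabolites
*m = 1…M* measured on the same donors, the locality score is the weighted
mean of absolute Spearman correlations

```
S(t_i) = Σ_m D_im^-2 (1 - p_Cim) |C_im|  /  Σ_m D_im^-2 (1 - p_Cim)
```

where *C<sub>im</sub>* is the Spearman correlation between transcript and
metabolite profiles, *p<sub>Cim</sub>* its p-value, and *D<sub>im</sub>*
the network distance of metabolite *m* from the enzyme on the
reaction-pair graph (incident metabolites have *D* = 1). Significance is
assessed by recomputing the score K = 10 000 times with randomly permuted
distance-matrix columns (correlations held fixed) and reporting
`p = #{S_rand ≥ S} / K`. Enzymes with *p* < 0.05 whose expression is also
age-dependent (gene–age Spearman *p* < 0.1, or BH-adjusted differential
*p* < 0.1) form the final hit table.

Around this core the package provides the full pipeline:

* exact-mass ion annotation ([M−H]⁻ and [M+F]⁻ adducts, 0.001 Da),
* quantile normalization and log2 transforms for both omics,
* Pearson ion–age correlation (|rho| > 0.25, Storey q < 0.01) and Welch
  old-vs-young tests (|log2FC| > 0.1, q < 0.05),
* QC filtering (≥50 % saturated/background), per-gene linear-model
  differential expression (|log2FC| > 0.25, BH p < 0.01),
* the recursive nested-subset hypergeometric pathway enrichment
  (minimum tail p over all significance-ordered prefixes of the hit
  list, Storey-corrected),
* a synthetic matched-omics generator with planted, network-localized
  effects and recorded ground truth.

## Worked example

```r
library(metlocal)
sim <- generate_dataset(sim_config(seed = 42))   # 23+23 donors, 20 planted enzymes
dir <- file.path(tempdir(), "ex"); write_dataset(sim, dir)
res <- run_pipeline(pipeline_config(input_dir = dir,
                                    out_dir = file.path(tempdir(), "run"),
                                    K = 10000, seed = 42))
report(res$out_dir)
```

```
  ions detected/annotated:    300 / 150
  age-correlated ions:        36
  differential ions:          38
  features (raw/after QC):    400 / 380
  significant transcripts:    21
  enriched pathways (m/g):    10 / 0
  enzymes scored:             192
  locality-significant:       24
  locality hits (age filter): 19

Top locality hits:
 transcript         S p_locality    rho_age        p_age     log2fc
      G0025 0.5372282     0.0001  0.6910035 1.063216e-07  0.9358610
      G0107 0.5375949     0.0001 -0.7289435 9.237829e-09 -0.9055048
      G0075 0.5096065     0.0002 -0.6732119 2.956783e-07 -0.9592789
      ...
```

Half of the 300 simulated ions are [M−H]⁻ ions of database compounds and
are annotated; the rest are noise. 18 of the 19 final hits are truly
planted enzymes (`sim$ground_truth$planted_enzymes`), i.e. genes whose
simulated expression change was wired into their distance-1 metabolites.
A published 21-gene reference hit table ships with the package
(`reference_locality_hits()`) and is reproduced exactly by
`filter_locality_hits()`.

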