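---
title: "Network locality scoring for matched metabolome-transcriptome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network locality scoring for matched metabolome-transcriptome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metlocal)
```

## The problem and the model

When tissue ages, both metabolite levels and the expression of
metabolic enzymes shift, but in mature human tissue these shifts are
mild — typically well under two-fold. Calling an enzyme "functionally
altered" from its transcript alone is therefore fragile. The locality
score asks a sharper question: does the enzyme's expression profile
*co-vary across donors* with the metabolites adjacent to it in the
metabolic network? A genuine change in enzymatic activity should perturb
the enzyme's own substrates and products first, so correlation
concentrated at short network distances is evidence of a functional
footprint, whatever its sign.

Formally, for transcript $t_i$ and measured network metabolites
$m = 1 \dots M$,

$$S(t_i) = \frac{\sum_m D_{i,m}^{-2}\,(1 - p_{C_{i,m}})\,|C_{i,m}|}
                {\sum_m D_{i,m}^{-2}\,(1 - p_{C_{i,m}})},$$

with $C_{i,m}$ the Spearman correlation between the transcript and the
metabolite across matched donors, $p_{C_{i,m}}$ its two-sided p-value,
and $D_{i,m}$ the network distance: $1$ for metabolites incident to the
enzyme's reactions, $1 + $ shortest-path length otherwise. $S$ is a
weighted mean of $|C|$, so $S \in [0, 1]$ and a single-neighbor
enzyme has $S = |C|$ exactly.

Significance comes from a permutation null that breaks the pairing
between distances and correlations while keeping both marginals: in
each of $K$ iterations one random permutation of the metabolite indices
is applied to the columns of $D$ (shared across all transcripts within
an iteration), the scores are recomputed with the correlations held
fixed, and

$$p(S(t_i)) = \frac{\sum_k \mathbb{1}\{S^k_{rand}(t_i) \ge S(t_i)\}}{K}.$$

The correlations are *not* recomputed under permutation — only the
distance weights move — which is exactly what the score's definition
implies: the null hypothesis is "the observed correlations are not
preferentially located near the enzyme", not "there are no
correlations". An enzyme is finally reported as a hit when
$p < 0.05$ *and* its expression is age-dependent (gene–age Spearman
$p < 0.1$, or BH-adjusted old-vs-young $p < 0.1$).

### Assumptions

* Donors are matched across omics; all correlations are computed on the
  shared sample set.
* Reaction directionality and stoichiometry are ignored; the
  reaction-pair graph is undirected and unweighted.
* Direction-agnosticity: the score uses $|C|$, so induction and
  repression count equally (metabolite pools may move either way when
  an enzyme changes).
* Unreachable metabolites carry zero weight and are excluded from both
  sums; permutations that empty a transcript's neighborhood are skipped
  with that transcript's $K$ reduced.

## The surrounding pipeline

The score sits at the end of a conventional two-omics pipeline whose
thresholds are fixed by the study design:

| stage | statistic | significance rule |
|---|---|---|
| ion–age association | Pearson rho, Storey q | \|rho\| > 0.25, q < 0.01 |
| ion differential | Welch t (old vs young), Storey q | \|log2FC\| > 0.1, q < 0.05 |
| transcript differential | per-gene OLS on group, BH | \|log2FC\| > 0.25, adj. p < 0.01 |
| pathway enrichment | recursive hypergeometric, Storey q | q < 0.01 |
| locality hit filter | permutation p + age evidence | p < 0.05 and (p_age < 0.1 or adj. p < 0.1) |

All inequalities are strict, matching the printed rules.

Ion annotation is exact-mass only: compound $M$ matches an ion at
observed $m/z$ when $|m/z - (M + \delta)| \le$ 0.001 Da, with
$\delta = -1.007276$ ([M−H]⁻) or $+18.998403$ ([M+F]⁻), the two ion
forms relevant for fluoride-modified negative-mode flow injection.
Isotopologue- and cross-correlation-based annotation evidence is out of
scope. Unannotated ions remain in every statistical family and in
enrichment backgrounds — the tested unit is the detected ion, not the
metabolite. For the network stage, ions are re-annotated onto the
network's compound set; when several ions hit one compound the smallest
absolute mass error wins, and an ion hitting several compounds feeds
all of them, flagged ambiguous.

The enrichment procedure evaluates the hypergeometric upper tail on
*every* significance-ordered prefix of the significant list (most
significant feature first, then the best two, and so on) and reports
the minimum p per pathway. The displayed classical enrichment term is a
point mass; a point mass is not a p-value, so the upper tail
$P(X \ge k)$ is used as the test statistic (a `pmf_only` switch
reproduces the literal term for comparison). The prefix minimum is an
optimistic statistic — its null distribution is not uniform — which is
why it is only used with the Storey correction across pathways and a
stringent q < 0.01 cut, and why the package tests it against an
exhaustive prefix-enumeration oracle rather than against a nominal
error rate.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `tolerance` | 0.001 | Da | instrument mass accuracy of the acquisition |
| `rho_min`, `q_corr` | 0.25, 0.01 | — | printed correlation rule |
| `fc_min_metab`, `q_diff` | 0.1, 0.05 | log2 / — | printed differential rule |
| `fc_min_gene`, `adjp_gene` | 0.25, 0.01 | log2 / — | printed transcript rule |
| `K` | 10000 | permutations | resolution 1e-4 on p, matching the reported minimum p |
| `lambda` | 0.5 | — | fixed-lambda Storey pi0; no smoother (see below) |
| `d_max` | unbounded | edges | the $D^{-2}$ decay already bounds influence; a cutoff is available |

## Numerical and design choices

* **Storey q-values.** $\hat\pi_0 = \min(1, \#\{p > \lambda\} /
  ((1-\lambda) n))$ at fixed $\lambda = 0.5$, multiplied into the BH
  cumulative-minimum transform. The smoother-based $\pi_0$ estimate is
  deliberately not implemented; at the pipeline's family sizes the
  fixed-lambda estimate is stable and transparent. Note the estimate
  can reach 0 when every p is small, collapsing all q to 0 — accepted
  as the formula's literal behavior.
* **Quantile normalization** delegates to
  `limma::normalizeQuantiles(ties = TRUE)`: ties within a column
  receive the mean of the reference values at their tied ranks. The
  operation is idempotent and equalizes the sorted columns exactly,
  both asserted to 1e-12 in the tests.
* **Normalization order, metabolome:** quantile normalization on raw
  intensities (it corrects per-sample loading on the scale the
  instrument reports), then $\log_2(x+1)$ so that fold changes are
  mean differences. A raw-scale mode is available
  (`log2_metab = FALSE`). Expression arrives on log2 scale and is
  quantile-normalized as-is, after QC removal (filtering first, so
  flagged features cannot distort the reference distribution).
* **Degenerate inputs.** Constant profiles have no defined correlation
  or t-statistic: primitives raise errors naming the feature, while
  matrix-level drivers exclude such features from the multiple-testing
  family with a warning rather than aborting a whole run. In the
  locality score, undefined correlations enter with $C = 0$, $p_C = 1$
  (minimal weight, zero contribution).
* **Permutation ties.** Permuted scores are compared with a 1e-12
  tolerance so that the analytically-tied case (all distances equal,
  every $S_{rand} = S$) reports $p = 1$ regardless of floating-point
  summation order. A p of exactly 0 is reported as computed — no
  pseudo-count — matching the score formula literally.
* **Permutation scheme.** One metabolite-index permutation per
  iteration, shared across transcripts, preserving each row's distance
  multiset. This is the direct reading of "randomly permuted versions
  of the distance matrix"; per-row independent shuffling would break
  the across-transcript correlation structure of the null but not its
  marginals.
* **Probe collapsing.** When several features share a gene symbol, the
  highest-mean-expression feature represents the gene in the locality
  analysis — the usual microarray convention when no probe quality
  information is available.
* **No empirical-Bayes moderation.** Transcript differential statistics
  use an ordinary per-feature linear model (algebraically the
  pooled-variance t-test; the identity is asserted to 1e-10 against
  `lm()` in the tests). With ~23 arrays per group, variance moderation
  changes ordinary statistics negligibly, and the explicit model keeps
  every number derivable by hand. This is the largest known numerical
  divergence from limma-based analyses of the same design.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the *statistical structure* the
pipeline exploits: two disjoint integer-age groups (20–25 / 55–66 y,
23 donors each, matching the matched-cohort size); a connected toy
reaction-pair network (spanning tree + 20 % extra edges, 150
metabolites, 200 enzymes with 1–3 incident metabolites); compound
masses on a 0.005-Da grid in 80–900 Da so annotation is provably
unambiguous at 3× tolerance; expression = baseline + group effect
(planted enzymes only, default 1 log2 unit) + N(0, 0.2²) noise + a
per-sample array offset that quantile normalization removes; and, for
each planted enzyme, distance-1 metabolites that track the enzyme's
standardized expression at correlation `coupling_strength` (default
0.8) with randomized sign, recorded in the ground truth. One [M−H]⁻
ion per compound carries the metabolite signal (mass error uniform
within ±0.0005 Da); surplus ions are unannotatable noise. QC artifacts
are spiked only on non-planted features, so the planted-signal
validation surface is never randomly destroyed by QC removal.

Not emulated: chromatography and ionization physics, isotopologues,
multiple adducts per compound (available as an option but off by
default), probe-level redundancy, donor covariates beyond age, and any
biological pathway structure in the planted effects (pathway labels
are arbitrary blocks). Passing tests on this generator therefore
demonstrate the *statistical machinery* — calibration of the
permutation null, recovery of network-localized coupling, FDR behavior
— not performance on real spectra, and effect sizes were chosen for
testability rather than biological realism (no published effect sizes
exist to emulate).

## Validation problem sizes

The shipped test suite validates, among ~40 properties:

* permutation p-values against exhaustive enumeration (≤ 5 metabolites,
  K = 10 000, 3·SE agreement);
* null calibration on 5 uncoupled cohorts (200 enzymes each, K = 1000):
  rejection rate at p < 0.05 within [0.03, 0.07];
* planted-enzyme recovery ≥ 80 % on average over 10 cohorts at coupling
  0.8, noise 0.2, 23+23 donors;
* recursive enrichment against brute-force prefix enumeration on 100
  randomized instances (exact);
* FDR behavior on 10 null cohorts: ≤ 1 % false positives at the
  correlation q < 0.01 and transcript adj. p < 0.01 rules;
* exact reproduction of the published 21-gene reference hit table by
  the locality hit filter.

These sizes keep the default suite around half a minute on one CPU
while leaving each check statistically meaningful.

## Known limitations

* The locality score depends on the completeness of the
  enzyme–metabolite incidence map; enzymes whose neighborhoods are
  unmeasured are skipped, not imputed.
* Exact-mass annotation cannot separate isomers; ambiguity is flagged
  but not resolved.
* The prefix-minimum enrichment p-value is anti-conservative by
  construction; interpret it only through its q-value.
* Storey's fixed-lambda pi0 is unstable for very small families
  (a handful of pathways); q-values there should be read with care.
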