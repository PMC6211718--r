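---
title: "Detecting differentially expressed subnetworks with subnetDE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially expressed subnetworks with subnetDE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetDE)
```

## Overview

`subnetDE` identifies gene subnetworks that are both *highly connected* — in
a weighted co-expression network primed with a priori gene–gene relations —
and *differentially expressed* between two phenotype groups.  This vignette
describes the statistical model behind each stage, the tunable parameters
and their defaults, the synthetic-data generator used for validation, and
the design decisions taken where the methodology leaves room.

## Stage 1: prior-primed network construction

Within one sample group (the "correlation source"), co-expression
similarity is the absolute Pearson correlation, $s_{ij} = |\mathrm{cor}(x_i,
x_j)|$, computed by `abs_pearson_similarity()`.  Using the absolute value
makes the network unsigned: strongly anti-correlated genes are considered
as connected as correlated ones.  Genes constant within the subset carry no
correlation information and are dropped with a report.

The central integration step multiplies the soft-thresholded similarity
with the binary prior indicator $p_{ij}$ (1 iff the pair has a known
relation, e.g. a PPI):

$$a'_{ij} = p_{ij} \cdot s_{ij}^{\beta}, \qquad \beta \ge 1.$$

The prior acts as a hard mask — only pairs with external evidence can be
connected — while the correlation, raised to the power $\beta$, sets the
connection strength.  Because $p_{ij}$ is binary, applying the power before
or after the mask is mathematically equivalent; the implementation applies
it to the similarity, which is the only reading under which optimizing
$\beta$ against the scale-free criterion is meaningful.  Graded priors
($p_{ij} \in (0,1)$) are deliberately not supported.

### Soft-threshold selection

$\beta$ is chosen so that the masked network approximates scale-free
topology.  `scale_free_fit()` bins the connectivities $k_i = \sum_{u \ne i}
a'_{iu}$ into 3–10 equal-width bins and regresses $\log_{10}$ frequency on
$\log_{10}$ mean connectivity over non-empty bins; the fit index is $R^2$,
negated when the slope is positive (a rising degree distribution is the
opposite of scale-free).  For each candidate power, `pick_soft_threshold()`
keeps the largest bin count whose $R^2$ reaches the target (default 0.8,
falling back to the best-fitting bin count), and returns the smallest power
whose kept fit meets the target — or, flagged, the best-fitting power if
none does.  The candidate grid is the integers 1–20.  Equal-width binning
and unweighted least squares are used throughout; equal-occupancy binning
would be a defensible alternative, but the equal-width convention is the
common one for degree histograms and is fixed here for determinism.

### Topological overlap

`topological_overlap()` computes

$$\omega_{ij} = \frac{l_{ij} + a'_{ij}}{\min(k_i, k_j) + 1 - a'_{ij}},
\qquad l_{ij} = \sum_{u \ne i,j} a'_{iu} a'_{uj},$$

with $\omega_{ii} = 1$ and connectivity sums excluding the diagonal.  TOM
measures how much two genes share neighborhood, which smooths the sparse
masked adjacency: two genes without a direct prior edge can still be
similar if they share primed neighbors.  $1 - \omega$ is the clustering
dissimilarity.

## Stage 2: module detection

The dissimilarity is clustered by average linkage (UPGMA, via
`stats::hclust`) and cut by `dynamic_tree_cut()`, a hybrid-style adaptive
procedure implemented in this package:

1. Merge heights are normalized to the span between their 5th percentile
   and maximum (a degenerate span maps all heights to 0).
2. Merges in the top `1 - cut_height` fraction of that range (default
   `cut_height = 0.99`) are always split: branches joining only at the very
   top of the dendrogram are never one module.
3. Below that, a branch is split when each sub-branch of admissible size
   has a *tight core* — the mean of its `min_size - 1` earliest normalized
   merge heights is at most `max_core_scatter` — and attaches to its parent
   with a *gap* of at least `min_gap`.  When only one sub-branch qualifies,
   the other is either recursed into (if large) or set aside (if smaller
   than `min_size`).
4. A terminal branch becomes a module if it has at least `min_size` leaves
   and a tight core; otherwise its leaves are set aside.
5. Set-aside leaves are assigned to the module whose core (the `min_size`
   members with smallest average within-module dissimilarity) they are
   closest to, provided that normalized distance is within
   `max_core_scatter`; the rest are labeled 0 (unassigned).

`deep_split` $\in \{0, \dots, 4\}$ (default 2) maps to `max_core_scatter`
$\in \{0.64, 0.73, 0.82, 0.91, 0.95\}$ with `min_gap = (1 -
max_core_scatter) \cdot 3/4$ — the standard parameterization of the hybrid
procedure; higher values split more aggressively.  Bit-compatibility with
any particular dynamic-tree-cut implementation is a non-goal; the
behavioral contract, enforced by the test suite, is recovery of planted
modules (adjusted Rand index $\ge 0.9$ on block dissimilarities, $\ge 0.8$
end-to-end on the demo data) and sensible degenerate behavior (a
structureless dissimilarity yields a single module; blocks below `min_size`
stay unassigned).  All tie-breaks are by lowest index; the stage has no
randomness.

`extract_subnetworks()` drops unassigned genes and modules outside
`[min_size, max_size]` (defaults 10 and 500, matching the gene-set size
filter of the enrichment stage) and annotates each retained module's edges
with TOM weight and a prior flag for export.

The default minimum module size of 10 is aligned with the enrichment-stage
lower bound, since smaller modules would be discarded there anyway.

## Stage 3: preranked enrichment screening

Genes are ranked by the SAM moderated statistic (`sam_statistic()`)

$$d_i = \frac{\bar{x}_{i2} - \bar{x}_{i1}}{s_i + s_0}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
\frac{SS_1 + SS_2}{n_1 + n_2 - 2}},$$

positive $d_i$ meaning up-regulation in group 2.  The fudge factor $s_0$
protects low-variance genes from dominating the ranking; the default rule
is the median of the $s_i$ (robust and parameter-free), with the original
percentile-search rule — minimizing the coefficient of variation of
window-wise MADs of $d_i$ over the $s_i$-percentile grid 0, 5, …, 100 —
available as `estimate_s0(method = "percentile_search")`.  Ranking ties are
broken lexicographically by gene identifier, making the ranked list unique.
The ranking statistic is pluggable: any named, signed per-gene score can be
passed to `rank_genes()`.

Each detected subnetwork is scored on this list by the weighted
running-sum enrichment statistic (`enrichment_score()`), with hit
increments $|r_j|^p / N_R$ (default weight $p = 1$; $p = 0$ gives the
classic Kolmogorov–Smirnov form), miss decrements $1/(N - N_H)$, ES the
maximal deviation (earliest position on ties), and the leading edge the
member genes at or before a positive peak (at or after a negative one).
Nulls are size-matched random gene sets drawn without replacement
(`null_es_distribution()`, default 1000 draws, cached per set size); with a
preranked list, gene-based permutation is the only available scheme.
$NES = ES / \mathrm{mean}(|ES_{null}|\ \text{of matching sign})$ and the
nominal p-value is the same-sign tail fraction, reported as 0 when the
observed ES exceeds every null (i.e. $p < 1/n_{perm}$); no $+1$ smoothing
is applied.  No FDR is computed inside this stage: the pipeline-level
permutation FDR below supersedes it and refers to the whole procedure, not
to the enrichment step alone.

Running the full construction–detection–screening chain with each group as
correlation source, and splitting each source's results by enrichment sign,
yields the four ranked lists (`run_pipeline()`), labeled source tag +
enriched-group tag (e.g. `AB` = source-A correlations, enriched in group
B).

## Stage 4: whole-pipeline permutation significance

`permutation_significance()` re-runs the *entire* pipeline on perturbed
input:

* **ppi scheme** — gene labels are shuffled on the fixed prior-network
  topology (`permute_prior_labels()`): degree sequence and component
  structure are preserved exactly, only the identity of the interaction
  partners is randomized.
* **gene scheme** — gene labels are shuffled over the fixed expression rows
  (`permute_expression_gene_labels()`): the correlation structure of the
  data is untouched, only its assignment to gene identities (and hence the
  agreement with the prior and with the ranking) is randomized.

Both schemes deliberately preserve network topology; a freer randomization
would produce an unrealistically favorable null.  All permuted subnetwork
NES values are pooled by sign.  For an observed subnetwork with score
$NES^*$, the nominal p is the fraction of same-sign pooled permuted NES at
least as extreme, and

$$FDR = \frac{\#\{|NES_{perm}| \ge |NES^*|\} / N_{perm}^{sign}}
{\#\{|NES_{obs}| \ge |NES^*|\} / N_{obs}^{sign}}$$

clipped to $[0, 1]$.  This pooled same-sign ratio estimator is a design
decision: the methodology prescribes comparing observed and permuted NES
populations without fixing the exact estimator, and this form is the
standard one for NES-based FDRs.  It is self-consistent (invariant to
duplicating the null pool) and, as the calibration test shows, yields
approximately uniform nominal p-values under a global null.  Permutation
replicates are seeded `seed + r`, so any subset can be reproduced
independently.  During permuted re-runs the observed soft-threshold power
is re-used per source by default (`beta_mode = "fixed"`) — cheaper and
conservative — with per-replicate re-optimization available as
`beta_mode = "full"`.

`select_significant()` truncates a ranked FDR list before the first rank
whose FDR both jumps by more than `jump_delta` (default 0.2) over its
predecessor and exceeds `fdr_ceiling` (default 0.25); the predecessor of
rank 1 is 0, so a list that opens high selects nothing.

## Stage 5: clinical follow-up

For a selected subnetwork, `signature_scores()` averages z-scored expression
(per gene, across the scored samples) over the leading-edge genes — only
those genes drive the enrichment score, so only they enter the signature.
Scores are compared across disease stages with the Mann–Whitney U test
(exact permutation p-value via a shift-algorithm convolution whenever
$n_A n_B \le 400$, valid under ties; tie-corrected normal approximation
otherwise) and related to survival by quartile splits
(`quartile_split()`, schemes Q1–2 vs Q3–4, Q1–3 vs Q4, Q1 vs Q2–4, boundary
ties to the low group) with Kaplan–Meier curves and the log-rank test
(via the survival package), Bonferroni-corrected.  Because a data-driven
merging of quartile groups "with similar survival" is not reproducible
as a rule, the `survival` command evaluates all three canonical schemes and
corrects across subnetworks × schemes — reporting everything rather than
silently picking the best split.

## The synthetic-data generator

`simulate_dataset()` produces the statistical structure the pipeline
assumes, with ground truth:

* **Expression** — module $m$ in sample group $g$ has a latent factor
  $e \sim N(\delta_{mg}, 1)$ per sample; a member gene is $\rho e +
  \sqrt{1-\rho^2}\,\varepsilon + b_g$ with $\varepsilon \sim N(0,1)$ and a
  gene baseline $b_g \sim N(8, 1)$ (log2-intensity scale).  Expected
  within-module gene–gene correlation is $\rho^2$.  Background genes are
  baseline plus $N(0, \sigma^2_{noise})$.
* **Prior network** — a seeded fraction `overlap` of each module's genes is
  "covered"; covered pairs are edges with probability `q_in`.  A
  preferential-attachment background graph (`pa_m` edges per new node,
  labels assigned in random order) emulates a scale-free but incomplete
  interactome.
* **Survival** — event times are exponential with rate $\lambda
  \exp(c \cdot score)$, administratively censored at a horizon, where
  $score$ is a sample's true module-1 latent factor.

The packaged `demo_spec()` — 2000 genes, 60 + 40 samples, six planted
modules of sizes 60–15 with loading 0.8 and mixed shift patterns (strong
and moderate shifts up in either group plus two nulls), 70% prior coverage,
`q_in` 0.9 — emulates a filtered two-group microarray study at a size that
runs end-to-end in seconds.  The generator does *not* emulate probe-level
noise, batch structure, matched sample pairing, or non-Gaussian expression
distributions; passing tests demonstrate that the pipeline recovers the
structure it models, not that it is robust to artifacts absent from the
model.

## Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` validate planted-module recovery
on the 2000-gene demo data, and run the permutation-heavy experiments — the
end-to-end power check (planted module attains top |NES| and the smallest
FDR under both schemes) and the global-null calibration (KS test of the
nominal p-values against uniformity) — at 100 whole-pipeline permutations
on 500-gene datasets (the `synthetic_spec()` defaults: 30 + 30 samples,
three 40-gene modules, 80% prior coverage).  These sizes were chosen as the
smallest at which all pipeline stages are exercised with comfortable
statistical margins on a single CPU; the pipeline itself has no
size-dependent switches, so behavior at larger scales differs only in
runtime.

## Numerical and degenerate-input conventions

* Quantile normalization is the mean-of-order-statistics scheme with ties
  receiving the mean of their target quantiles (delegated to
  `limma::normalizeQuantiles`); it is idempotent, and a single-column
  matrix is returned unchanged with a warning.
* Readers reject missing cells by default (an optional row-drop mode
  exists); duplicate gene rows keep the highest-mean row — a minimal
  stand-in for probe collapsing, which is out of scope, with no claim of
  fidelity to any upstream collapse rule.
* Edge lists are coerced to simple undirected graphs: self-loops dropped,
  duplicate edges collapsed, each with a warning.
* All matrices are dense; gene order is preserved from input everywhere for
  determinism.
* Similarities are clipped into $[0, 1]$ against rounding excursions; TOM
  is clipped from above at 1.
* Every stochastic step (GSEA nulls, permutation replicates, generators)
  takes an explicit seed, and seeded evaluation never leaks RNG state to
  the caller.

## Known limitations

* The prior is a hard binary mask: genes without any prior edge can never
  enter a module, so results inherit the incompleteness of the relation
  network.
* Block-wise computation for very large gene universes (> 20k) is not
  implemented; the dense TOM is quadratic in memory.
* Signed networks, soft priors, module eigengene post-processing and
  internal GSEA FDRs are intentionally out of scope.
* The permutation FDR estimator pools across subnetwork sizes; with very
  heterogeneous size distributions a size-stratified null could be more
  exact.
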