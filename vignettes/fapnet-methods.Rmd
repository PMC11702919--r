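---
title: "Methods: network discovery of activity-dependent regulators of FAP adipogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network discovery of activity-dependent regulators of FAP adipogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Intra- and intermuscular adipose tissue (IMAT) accumulates in aging muscle
and is fed by the adipogenic differentiation of fibro-adipogenic progenitors
(FAPs). Resistance exercise suppresses, and immobilization promotes, the FAP
adipogenic program. `fapnet` implements a network-medicine workflow that
starts from per-dataset transcriptomic *response profiles* — the log fold
change of post-intervention versus baseline expression in each study — and
asks which gene acts as the activity-dependent regulator of a
phenotype-associated gene set:

1. filter and normalize expression data, compute per-dataset logFC profiles;
2. score the phenotype gene set in each profile (ssGSEA) and extract its
   leading-edge genes (preranked GSEA);
3. build a weighted co-expression network across datasets (soft threshold,
   topological overlap, module detection, eigengenes) and find the module
   enriched for the phenotype set and its EdgeCount hub;
4. propagate from the leading-edge genes by random walk with restart (RWR),
   annotate each propagated neighborhood with pathways, and call the gene
   sitting in the most consistently enriched pathways the *functional hub*;
5. "squeeze": intersect pathways reached forward (from the phenotype genes)
   and backward (from the functional hub) to nominate mediators;
6. quantify downstream statistics — PC1 condition-separation scores with
   leave-one-out robustness, exact Mann-Whitney tests, and the percentage
   rejuvenation of a readout anchored at elderly (0%) and young (100%)
   baselines.

Because the original cohorts are external downloads, the package ships a
synthetic-data generator with planted structure; every claim the test suite
makes is a claim about recovering that planted structure.

## The synthetic response model

`synthetic_design()` fixes the study conditions: 2,000 genes, planted
modules of sizes 300/200/150/100/50, five exercise and two immobilization
datasets, effect size 1 logFC, residual noise SD 0.3. Gene g in module m of
dataset d follows

y_gd = effect * u_m * s_d + s_d * z_{m,d} + eps_gd,

with `u_m` in {+1, -1} alternating over modules, `s_d` = +1 (exercise) or -1
(immobilization), and `eps ~ N(0, noise_sd^2)`. Background genes are pure
noise.

`z_{m,d}` is a module-specific latent dataset factor (SD `module_sd = 2`).
It exists because a model with only the condition term makes every
same-direction module an exact copy of the same mean profile: correlation
cannot distinguish them even in principle, and no module detector could
recover the planted partition. The factor is drawn per module, then

* **orthogonalized** against the intercept and the condition contrast, so
  the realized condition effect is *exactly* `effect * u_m * s_d` and every
  module has identical realized signal variance (without this, the realized
  variance lottery across modules lets a single module monopolize the
  top-5000-edge network); and
* **multiplied by `s_d`**, so that flipping all condition signs negates
  every module profile exactly — a symmetry the tests assert.

`module_sd = 2` (twice the mean effect) mirrors the large between-study
heterogeneity of exercise transcriptome responses; it also sets the
between-module correlation (same-direction modules share only the condition
response, |r| ≈ 0.17) at a level where modules are distinct entities.

The planted hub is one gene of module 2 whose profile is the module mean
plus `N(0, (noise_sd/10)^2)`. With only seven datasets, the sampling noise
of a correlation coefficient is large (SD about 0.4 at n = 7), and repeat
simulation shows a hub with noise `noise_sd/4` is the most module-correlated
gene only ~55–60% of the time — too weak to define a recoverable planted
truth; at `noise_sd/10` the recovery is essentially complete. The fraction
is exposed as `hub_noise_frac`.

Decoy pathways are drawn from the complement of the planted mediator and the
phenotype set. Decoys that accidentally share members with the planted
pathways would not be decoys: any of their members lying in the hub module
inherits real enrichment signal, which turns "contribution to consistent
pathways" into a coin flip between the hub and coincidental double members.

## Preprocessing choices

* The count filter keeps a gene iff its CPM exceeds
  `min_count / median(libsize) * 1e6` in at least k samples (k = smallest
  group size) and its total count reaches `min_total` — the documented
  two-threshold core of the standard `filterByExpr` logic (min count 10),
  reimplemented so the rule itself is testable against hand evaluation.
* The intensity filter keeps genes at or above the 0.25 quantile of all
  matrix values in at least k samples. The quantile is a package choice; the
  soft filter it emulates is described only qualitatively in the microarray
  literature.
* TMM follows the trimmed, precision-weighted mean of M-values with 30%/5%
  trims, reference column closest to the mean upper-quartile, and factors
  rescaled to geometric mean 1. The test suite cross-checks it against
  edgeR to 1e-6 on random counts.
* Differential expression is a two-group moderated t: pooled per-gene
  variances are shrunk toward a scaled-F prior fitted by the method of
  moments on log variances (trigamma inversion), p-values use d + d0 degrees
  of freedom. This is the statistical shape of the standard
  empirical-Bayes test, fully specified here so a formula oracle can check
  it; the suite also cross-checks against limma on random data. Counts
  enter as log2(CPM + 0.5) on TMM-effective library sizes; the 0.5 offset
  avoids log 0.
* `rank_normalize` maps descending logFC to ranks scaled into (0, 1] with
  average ties; the strongest up-regulated gene gets the smallest value.
  `ssgsea` consumes exactly this convention (genes walked top-rank first,
  hit weights `value^alpha`, default alpha 0.25 per the single-sample GSEA
  convention; the exponent is configurable because published descriptions
  leave it open).

## Enrichment

Preranked GSEA uses the classic running sum (hits add |score|^weight
normalized to 1, misses subtract 1/(N − N_hit)); ES is the maximum absolute
deviation from zero, ties resolving to the positive peak. Significance comes
from gene-set permutation (random same-size sets), because with a handful of
datasets phenotype permutation is impossible; NES divides ES by the mean
magnitude of same-sign null scores, p is floored at 1/(n_perm + 1) and never
zero. The leading edge is the set members at or before the peak (positive
ES) or at or after the trough (negative ES). Over-representation uses the
upper-tail hypergeometric against an explicit universe with BH adjustment
across the collection.

## Co-expression network

Pearson correlation on raw logFC profiles (rank normalization is reserved
for enrichment inputs) feeds an unsigned adjacency |cor|^beta (signed mode
available). `choose_soft_threshold` scans powers 1–20 and picks the smallest
whose connectivity distribution fits scale-free topology with R² ≥ 0.8 *and
a negative slope*; the sign requirement is essential — dense low-power
networks can produce high-R² fits with *increasing* frequency, which is not
scale-free topology, and accepting them collapses the topological overlap
contrast (the canonical implementation signs its R² for the same reason).
If no power qualifies, the best-fitting power is used with a warning; with
seven noisy datasets this is common and benign.

TOM follows the standard formula `(l_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij)`
and 1 − TOM is the clustering dissimilarity. Module detection is
average-linkage hierarchical clustering with a simplified dynamic cut:

1. a static cut at the `0.99 − 0.1 * deep_split` quantile of merge heights
   (deep split 2, minimum module size 30 — the conventional defaults);
2. each resulting cluster's subtree is recursively re-cut at its largest
   internal merge-height gap whenever that gap exceeds `gap_factor` (25)
   times the median successive gap; pieces below `min_size` are left
   unassigned. A cut is only accepted if it leaves at least one component
   of module size — the widest gap can sit at the very bottom of a subtree
   (a chance near-duplicate gene pair), where cutting would shatter the
   cluster into singletons; qualifying gaps are tried widest-first and the
   cluster is kept whole if none yields a viable split.

The recursion cuts at the *largest internal* gap rather than at the top
merge because average linkage chains background genes onto real clusters
one leaf at a time: the top merges of such a cluster have tiny gaps while
the informative gap (between within-module merges and everything above)
sits lower in the subtree. `gap_factor` separates the two regimes: inside a
homogeneous module the largest successive gap is a small multiple of the
median, while a cluster that glues two modules or a module plus a background
chain shows a gap two orders of magnitude above the median. The value 25 was
chosen by examining both regimes under the generative model. The full
dynamic hybrid tree cut is deliberately not reimplemented.

Module eigengenes are the first principal component of the
gene-standardized module submatrix, sign-aligned with the module mean
profile. The hub gene maximizes EdgeCount (incident edges) in the module's
top-pair edge list, with ties broken by summed incident weight then
lexicographically.

**Edge density for hub extraction.** The published default of 5,000
co-regulated pairs refers to a module of more than a thousand genes —
under 1% of its pairs. Drawing 5,000 edges from a 200-gene module (25% of
its pairs) saturates EdgeCount: nearly every central gene attains
near-maximal degree and the argmax becomes sampling noise. The pipeline
therefore caps the module edge list at `module_edge_density` (5%) of the
module's pairs, with 5,000 as the ceiling. The global propagation network
keeps the 5,000-edge default.

## Propagation

`rwr` iterates `p ← (1 − r) W p + r p0` on the column-stochastic transition
matrix (dangling nodes get self-loops) to an L1 tolerance of 1e-10, with
restart r = 0.7 — the convention of the multilayer RWR literature, exposed
in `propagation_config()`. The affinity vector provably sums to one, and the
iterative fixed point matches the closed-form linear solve to 1e-8 in the
test suite.

GSEA-guided propagation runs one RWR per seed gene (mirroring repeated
single-gene pseudo-activation), annotates each top-100 neighborhood by
hypergeometric ORA against the pathway collection (universe = network
nodes, FDR gate q < 0.05), and intersects the per-seed significant sets.
The functional hub is the non-seed candidate contained in the most
consistent pathways, ties broken by mean affinity across runs. Seeds are
excluded from candidacy: a seed's own restart mass dominates its affinity,
and the method's point is to discover a regulator distinct from the seeds.

The squeeze step intersects forward-consistent pathways with the pathways
significant in a backward run seeded at the candidate regulator. The
backward neighborhood uses the positive-affinity rule (every visited gene,
floored at 1/(10 n)) rather than the top-100 cut: a hub reaches its whole
module nearly uniformly, and truncating its neighborhood at 100 genes
underpowers the backward annotation, whereas the visited-gene convention
matches how backward pseudo-activation is described (hundreds of visited
genes feeding pathway annotation).

The pipeline's propagation network is the union of the globally top-5,000
TOM pairs and the phenotype module's own edge list. With a handful of
equally tight planted modules, the global top-5,000 can be monopolized by
whichever module's correlation tail happens to run highest in a given
cohort; appending the (much smaller) module edge list guarantees the module
under study is represented without changing the network elsewhere. The
topology-sensitivity analysis rebuilds the network at 5,000–100,000 edges
(clipped to the available pairs) with the same augmentation and tracks the
affinity rank of the target gene from every seed.

## Downstream statistics

PC1 scores center each gene across datasets and use the first right
singular vector, sign-fixed so the largest-|loading| gene loads positively;
leave-one-out stability is the minimum across folds of |r| between retained
scores and the full-data scores. The Mann-Whitney U test enumerates the
exact null distribution of the midrank sum by dynamic programming for
combined n ≤ 25 (ties handled exactly, two-sided by doubling the smaller
tail, capped at 1) and falls back to the tie-corrected normal approximation
beyond; with two versus five datasets the smallest achievable exact
two-sided p is 2/21 ≈ 0.095, which the implementation reports honestly
together with a small-sample warning rather than pretending significance is
attainable. Linear fits are OLS with the slope's t test, a Shapiro-Wilk
residual-normality p and the residual-fitted correlation as diagnostics.
Percentage rejuvenation is `100 (mean(exercise) − mean(elderly)) /
(mean(young) − mean(elderly))`; values outside [0, 100] are legitimate and
preserved.

## Problem sizes in the shipped tests

The suite exercises the full default design (2,000 genes, 7 datasets) in a
100-replicate recovery study, and smaller designs (a few hundred genes)
where only the orchestration is under test; oracle-equivalence checks run on
instances up to 50 genes (GSEA/ssGSEA), 30 genes (TOM), and 200 nodes
(RWR), and null calibrations use 200 replicates. These sizes were chosen so
the whole suite completes in minutes on a laptop while keeping every
recovery claim at the full design scale.

## What the synthetic benchmark does and does not show

The generator emulates block-correlated response modules, a planted hub, a
planted condition-discriminating set, and a mediator pathway, under additive
Gaussian noise and equalized module signal. It does not emulate platform
batch effects, sex stratification (a sample-sheet column only),
heavy-tailed counts in the logFC domain, correlated background genes, or
modules of unequal tightness. Passing the recovery criteria therefore shows
the pipeline's stages compose correctly and recover structure that is
present at realistic noise; it does not certify performance on real
meta-analytic cohorts, where module separation and pathway annotation
quality are the binding constraints.

## Known limitations

* With seven datasets, correlations are high-variance; the soft-threshold
  scan usually ends at the argmax fallback (with a warning) rather than a
  clean R² ≥ 0.8 fit.
* The simplified dynamic cut has one tuning constant (`gap_factor`); trees
  whose informative gap is less than ~25x the median merge gap will not be
  split further.
* Exact Mann-Whitney p-values below 0.05 are unattainable at 2-versus-5;
  the package reports the statistic and the attainable floor instead of
  stars.
* Phenotype-label permutation GSEA and module-preservation statistics are
  out of scope.
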