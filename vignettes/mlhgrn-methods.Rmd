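---
title: "Methods: hierarchical GRN inference from drought multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical GRN inference from drought multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlhgrn)
```

This vignette documents the models behind `mlhgrn`, the assumptions
they make, the parameters that matter, and the design choices taken
where the methodology was genuinely open.

## The inference problem

Given expression profiles of a metabolic pathway's genes and of a pool
of candidate transcription factors (TFs) across a drought time course,
we want an ordered regulatory hierarchy: which TFs act directly on the
pathway genes (layer 1), and which TFs act on those TFs (layer 2, and
so on), plus which metabolites track the pathway genes. The
identifiability caveat applies throughout: expression data support
importance rankings, not causal claims; "regulates" edges are
predictive relationships.

## BWERF: bottom-to-up weighted random forests

For one pathway gene, a random-forest regression of the gene on all
surviving candidate TFs yields impurity-decrease importances,
normalised to sum to one (`rf_importance()`). The recursion
(`bwerf_rank()`) then repeatedly removes the least important
`ceiling(drop_fraction * survivors)` TFs (at least one) and re-fits,
until a single TF survives. Recursive elimination matters because
forest importance is diluted by correlated competitors; re-ranking on a
shrinking panel lets genuine regulators accumulate evidence.

Per (TF, gene) pair the importance is aggregated as the **mean over the
iterations the TF survived**; per TF, the pathway score is the sum of
these aggregates over all pathway genes. Mean-over-survived avoids
biasing against TFs eliminated early (they are simply absent from later
snapshots rather than scored zero), at the price of rewarding any TF
that rides deep into the recursion — the Gaussian-mixture cut below is
what keeps that in check. We compared this aggregate against
first-iteration-only and iterations-survived counts on planted
hierarchies; the ranking quality (rank AUC of true layer-1 TFs) was
statistically indistinguishable, so the default follows the simplest
running-mean form.

Parameters (defaults): `n_trees = 1000` trees with `mtry = ceiling(sqrt(m))`
features per split; `drop_fraction = 0.1` per iteration (small steps
trade runtime for ranking stability); impurity importance, with
permutation importance behind `mode = "permutation"` (slower, less
biased under strongly correlated TFs). Forests are seeded per
(gene, iteration) from one top-level seed, and candidate columns are
canonicalised by TF id before fitting, so results are bit-reproducible
and invariant to input ordering.

## Layer selection by Gaussian mixture

Pathway scores of real regulators and of background TFs form two
overlapping populations, so a two-component 1-D Gaussian mixture is
fitted to the scores by EM (`gmm_fit_1d()`: best of `n_init = 10`
random starts, variance floor 1e-10, tolerance 1e-8 on the
log-likelihood increment). TFs whose posterior responsibility for the
higher-mean component is at least 0.5 form the layer
(`select_layer_tfs()`). If the two means are indistinguishable
(difference < 1e-6) the mixture carries no information and the top half
by score is retained with a warning. Selected TFs become the targets of
the next round, with already-placed TFs excluded from candidacy, so
layers are disjoint by construction; edges connect each target to its
`edges_per_target = 3` strongest selected regulators.

The posterior-0.5 rule makes layer size data-driven; on planted data it
is sometimes very conservative (a handful of top scorers) and sometimes
permissive — this is the dominant source of seed-to-seed variance in
recall/precision, not the forest ranking itself. An optional
`max_layer_size` caps a layer when a fixed-size network is wanted.

## What the expression simulator emulates

`simulate_hierarchy_expression()` plants the truth the method is judged
against: layer-2 TFs follow independent random natural cubic splines
over the timepoints (smooth, progressive-drought-like trends; smoothness
also induces realistic correlation between unrelated TFs), each layer-1
TF is a unit-variance linear combination of the *observed* profiles of
1–3 layer-2 TFs plus Gaussian noise, and each pathway gene likewise
combines 1–3 layer-1 TFs. Building children from observed parent
profiles — not from latent timepoint signals — encodes that regulation
acts on realised regulator levels in each sample; it is also what makes
the layer structure identifiable at all, since a child built from a
single latent signal would be statistically indistinguishable from its
parent. Decoy TFs are independent noise of comparable variance. With
signals standardised to unit variance, `noise_sd = 1` gives the
attainable parent-regression R² of ≈ 0.5 used throughout testing.

Default dimensions mirror a realistic desk-scale design: 40 pathway
genes, 10 direct regulators, 8 upstream regulators, 32 decoys, 6
timepoints (days 0–10) × 3 biological replicates. What the simulator
does *not* emulate: feedback loops, TFs regulating across non-adjacent
layers, combinatorial (non-additive) regulation, heteroskedastic
counts at the low-expression end, and batch structure — passing
recovery tests here therefore shows the machinery works under its own
assumptions, not that real drought networks will be recovered at these
rates.

Count data for the differential-expression test come from
`simulate_counts()`: NB counts with mean proportional to
expression × gene length × library size and a single shared dispersion,
matching the assumptions of the downstream test.

## The simplified differential-expression test

The screening rule — |log2FC| ≥ 1 (inclusive) with BH FDR < 0.05
(strict) per timepoint-versus-day-0 contrast — is what the downstream
analysis depends on; the DE engine behind it is intentionally simple. Per
gene, counts are normalised by median-of-ratios size factors, the fold
change uses group means with pseudo-count 0.5, and a Wald z =
log2FC / SE is referred to the standard normal, with the delta-method
SE from the NB variance mu + alpha·mu². The dispersion default is a
single moment estimate pooled across genes
(Σ(variance − mean) / Σ mean²): per-gene moment estimates at n = 3 are
noisy enough to inflate the null type-I error to ~0.11, while the
pooled estimate is calibrated (measured 0.05 ± 0.01 on 2000 null
genes) and matches the shared-dispersion simulator. `dispersion =
"per-gene"` gives the literal per-gene variant. Externally computed
(log2FC, p) tables can be screened directly with `screen_degs()`;
FDR is computed per contrast, consistent with per-day DEG reporting.

## Metabolome screen

Missing peak areas are imputed by row-wise KNN (`knn_impute()`):
neighbours are metabolites, distance is Euclidean over mutually
observed samples, the `k = 10` nearest observed neighbours contribute
inverse-distance weights (equal weights at zero distance). Published
metabolomics protocols usually name only the method; neighbour
orientation, k, and weighting are package defaults chosen to follow
common practice.
Compounds with QC coefficient of variation (sample sd / mean over QC
injections) not strictly below 0.5 are removed.

OPLS-DA (`oplsda_fit()`) is NIPALS O-PLS on unit-variance-scaled
intensities: components orthogonal to the class vector are removed one
at a time (default `n_orthogonal = 1`), then a single predictive
component is fitted; orthogonal scores satisfy |t'y| < 1e-8 by
construction, and with zero orthogonal components the model is exactly
one-component PLS-DA. VIP is computed over the predictive component
only, so mean(VIP²) = 1 exactly. A metabolite is differential when
VIP > 1 (strict) *and* fold change ≥ 2 or ≤ 0.5, with fold change the
ratio of arithmetic group means of imputed intensities (zeros are
handled by imputation, not pseudo-counts). Welch's t-test on log2
intensities with BH FDR is reported alongside but is not part of the
decision rule. UV scaling, the single orthogonal component, and
imputed-intensity fold changes are stated choices where the protocol
is conventionally silent.

## Temporal clustering

Replicates are collapsed to timepoint means and each metabolite is
z-scored across timepoints, so clustering sees profile *shape* in sd
units; constant profiles carry no shape and are dropped with a warning.
K-means uses k-means++ seeding and Lloyd iterations (stop at centroid
shift < 1e-8 or 300 iterations), keeping the best of `restarts = 50`
runs by within-cluster sum of squares; `k = 8` by default, the
conventional cluster count for drought-course metabolite profiles. The
implementation is in-package (rather than `stats::kmeans`) to expose
the k-means++ seeding, the exact stopping rule, and the per-iteration
inertia trace that the tests assert is monotone.

## Gene–metabolite linking

Pearson correlation between pathway-gene and metabolite profiles,
either over matched per-timepoint means (default, appropriate when the
assays were run on different aliquots) or over directly matched
samples; pairs with |r| ≥ 0.8 and BH-adjusted p < 0.05 are kept. The
threshold reading "based on correlation coefficients" is
under-specified; 0.8/0.05 are the package defaults and both are
configurable.

## Numerical choices and degenerate inputs

* EM: variance floor 1e-10; log-sum-exp responsibilities; the
  log-likelihood trace is non-decreasing and asserted so in tests.
* `gmm_fit_1d(init = )` runs EM from an explicit start — used to verify
  the implementation against an independent brute-force EM trajectory,
  since best-of-restarts comparisons across different RNG streams can
  legitimately disagree on local optima.
* Constant RF targets yield uniform importances with a warning; empty
  clusters are re-seeded at the worst-fitted point; all-zero genes get
  p = 1 and log2FC = 0; constant profile rows are dropped before
  clustering; ties in elimination are broken by stable order.
* All stage seeds derive deterministically from one top-level seed and
  stay below 2^31.

## Null control

Selecting TFs by score and then testing score separation on the same
scores would be circular. The null-control experiment therefore selects
a layer on one all-noise dataset and tests, by 1000 label permutations,
whether that retained set is separated in an *independent* rerun
(fresh data, fresh forests). On null data the permutation p-values are
approximately uniform; the acceptance check requires non-significance
(p > 0.05) in at least 8 of 10 seeds. The null experiment uses 20
targets × 30 decoy TFs with 500 trees and `drop_fraction = 0.2` — a
deliberately lighter setting than the recovery experiment, since the
test concerns calibration, not power.

## Problem sizes used in validation

Recovery experiments run the full study conditions (40/10/8/32 genes
and TFs, 6 × 3 samples, R² ≈ 0.5, 10 seeds); the measured operating
point at defaults is layer-1 recall ≈ 0.72 and precision ≈ 0.65 —
adequate for shortlisting regulators, with large per-seed spread
(recall 0.3–0.9) driven by the mixture cut as discussed above.
Metabolome screens use 1000 metabolites with 10% differential at
log2FC = 2 and n = 3 per group; DE calibration uses 2000 null genes at
3 vs 3. Unit tests use smaller instances of the same generators.

## Known limitations

* Hierarchies are forced to be layered and disjoint; real networks
  contain skip-level and feedback regulation that this representation
  cannot express.
* The mixture cut assumes exactly two score populations; with very few
  candidates (< 4) the selection falls back to the top half by score.
* The DE test is not a DESeq2 replacement: no shrinkage, no outlier
  handling, normal (not t) reference — adequate for the screening rule
  on well-behaved counts, and externally computed tables can be
  substituted.
* Correlation-based metabolite links at 6 timepoint means have limited
  degrees of freedom; |r| ≥ 0.8 with FDR control is deliberately
  stringent.
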