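---
title: "Transcriptome-profile subtyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-profile subtyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gliotype implements an unsupervised-then-supervised workflow for calling
transcriptomic subtypes of gliomas from a standardized gene-by-sample
expression matrix, together with the downstream statistics used to
characterize the resulting groups. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the synthetic cohort
the package validates itself on, and the design decisions that were
genuinely open.

## Density-based consensus clustering (DBU)

A single embedding of a tumor cohort is fragile: the picture depends on
which genes happen to dominate the distance metric. The DBU procedure
therefore repeats a subsample-embed-cluster cycle many times and lets the
iterations vote:

1. draw `genes_per_iteration` genes at random (without replacement);
2. embed the samples in 2-D with UMAP (`n_neighbors = 5`, `min_dist = 0`,
   `metric = "manhattan"` in gene space);
3. cluster the embedding with DBSCAN (`min_points`, `eps`), recording label
   0 for noise;
4. discard iterations whose cluster count differs from the expected number
   of groups (the modal count when `expected_groups = "auto"`);
5. align cluster labels across iterations (labels are arbitrary per
   iteration) and form a per-sample plurality vote.

A sample is *ambiguous* when fewer than 70% of the retained iterations
agree on one cluster, or when its most common label is DBSCAN noise. The
comparison is strict — exactly 70% support is still a confident call — and
the vote denominator is the number of retained, aligned iterations.

**Label alignment.** Cross-iteration alignment is automated: each
iteration's labels are first canonicalized (clusters renumbered by first
occurrence, making everything invariant to arbitrary label permutations),
then matched to a reference iteration by Hungarian assignment on the
cluster-overlap contingency matrix (`clue::solve_LSAP`). The reference is
the retained iteration with the highest mean adjusted Rand index against
all others. A manual-reorientation step, as a human analyst might perform
by inspecting a heatmap of iterations, is not reproducible and is not
provided.

**DBSCAN.** Run on the 2-D embedding with Euclidean distance (the
manhattan metric applies to UMAP's input space). The implementation is the
classic algorithm, written in the package; a point is core when at least
`min_points` points (itself included) fall within `eps`. `min_points`
should be on the order of a third of a typical group size — 100 for a
~1000-sample cohort, 25 for the 400-sample synthetic cohort. When a group
is re-clustered with `subcluster_group()`, `min_points` is rescaled
proportionally to the subset size.

**Choosing eps.** `eps = "auto"` takes the knee (maximum discrete
curvature, after normalizing both axes and lightly smoothing) of the sorted
k-th-nearest-neighbor distance curve with `k = min_points`. In practice the
per-iteration knee estimate is noisier than a single fixed radius, so the
package's own analyses fix `eps` once from inspection of k-distance curves
(1.55 for the reference full-scale cohort; 1.0 for the synthetic cohort's
embeddings) and keep the knee rule available as a starting point. Numeric
`eps` bypasses the knee search entirely.

**UMAP settings.** The neighborhood and distance parameters are consumed as
given; the package does not re-run the visual grid search that produced
them. Embeddings are computed single-threaded from a per-iteration derived
seed, so runs are bit-reproducible.

## Gene signature and model dictionary

The supervised side compresses the consensus classes into a reusable
classifier. The signature combines

- a *curated* list supplied by the analyst (domain genes, exempt from
  pruning at signature level), and
- an *RFE-selected* complement: candidates are the top one-vs-rest
  differentially expressed genes per class (Welch t statistic,
  Benjamini-Hochberg within contrast), then recursive feature elimination
  with a linear SVC removes `step = 5` genes per round — ranked by the sum
  of squared one-vs-rest weights — down to a target size (`n_select`).

Signature genes are partitioned into six expression-pattern groups by
k-means (50 restarts, fixed seed) on each gene's z-scored per-class mean
profile: the phrase "expression differences among the subtypes" fixes the
feature space, and k-means is the least-structured clustering of it.

Each of the `n_models` dictionary entries then half-samples every pattern
group (rounding down; the remainder stays available to other entries) and
runs RFE on the pooled half, this time stopping at the *smallest gene set
attaining the maximal cross-validated accuracy* — ties go to the smaller
set. Group-wise half-sampling keeps every expression pattern represented in
every entry while decorrelating the entries, which is what "democratizes"
gene usage across the ensemble. Entries are finally scored by stratified
threefold cross-validation and dropped below a 95% mean-accuracy floor.

Whether the original procedure optimized training or cross-validated
accuracy inside per-model RFE is not determinable; cross-validated accuracy
was chosen, as the less overfitting-prone reading. The linear SVC is built
one-vs-rest from binary `e1071::svm` fits (linear kernel, cost 1, no
rescaling — inputs are already z-scored); prediction takes the largest
one-vs-rest decision value.

## Ensemble classification (ETC)

For in-cohort calls, samples are split into four folds stratified by
consensus class; every dictionary entry is trained on three folds (never on
ambiguous samples) and votes on the held-out fold, so no sample's call ever
uses a model that saw it. Votes are combined by plurality with a
confidence score: `p1/p2`, the vote share of the most popular class over
the second most popular. Calls require confidence strictly greater than 3;
a score of exactly 3, or an exact top tie (confidence 1), is ambiguous.
Unanimity (`p2 = 0`) is treated as infinite confidence — the formula is
undefined there, and unanimity is the maximal-confidence case.

For external cohorts, `fit_final()` trains every entry on all labeled
samples. When the new platform lacks some signature genes,
`predict_external()` drops the missing genes from each affected entry and
*refits* that entry on the training cohort restricted to the surviving
genes; entries left with fewer than 2 genes abstain, and the vote
denominator is the number of voting entries. Refit-on-intersection was
chosen over zero-imputation because zero-filling standardized features
shifts linear decision scores systematically, while refitting preserves
each entry's decision geometry on the genes that remain. Votes are hard
class predictions, not margins.

## Downstream characterization

- **Mutation enrichment**: per gene and class, a one-vs-rest 2x2
  chi-squared without continuity correction (expected cells < 5 are
  flagged, not corrected), BH-adjusted across all gene-class tests; genes
  never mutated are removed first.
- **Survival**: Kaplan-Meier per class, log-rank across classes, and Cox
  proportional hazards (Efron ties) against a reference class; median
  survival is "not reached" when the curve never crosses 0.5; classes with
  zero events get non-estimable hazard ratios with a warning.
- **Purity**: median [IQR] per class plus one-way ANOVA; ambiguous samples
  are kept as their own group here, because low purity is a candidate
  explanation for ambiguity.
- **Concordance**: percent agreement between two classifications under an
  optimal one-to-one matching of class labels (Hungarian assignment on the
  contingency table), which makes the statistic invariant to class naming;
  a semantic mapping can override the automatic matching. Ambiguous samples
  are excluded by default.

## The synthetic cohort

Every stage is validated on generated cohorts with known truth. The
default configuration (`cohort_config()`): 400 samples, 2000 genes, four
subtypes with prevalences 0.40/0.25/0.22/0.13, 200 informative genes with
tumor-profile shifts of magnitude 2 (in pre-standardization noise-sd
units) and independent random signs per gene and subtype. Expression is a
purity mixture

    x = p (mu_subtype + e1) + (1 - p) (nu + e2),    e1, e2 ~ N(0, 1),

standardized gene-wise afterwards. The normal-tissue profile `nu` carries
magnitude-6 shifts on 1500 of the 2000 genes — non-malignant brain differs
from glioma across much of the transcriptome, and it is exactly this broad
normal program that makes purity dilution visible to clustering. The
fourth subtype copies the second subtype's tumor profile and differs only
through a lower purity distribution (Beta median 0.60 vs 0.77), emulating
a neuron-rich, few-malignant-cells group. Mutations live in a separate
gene namespace (five dedicated genes per subtype, odds ratio 6 over a 10%
background). Survival is exponential with per-subtype log hazards
(defaults 2.4/0/0.35/0, baseline hazard log(2)/80 per month, i.e. a
median of 80 months at the reference) and uniform administrative
censoring calibrated to a 30% marginal rate.

What the generator deliberately idealizes: purity spread within subtype is
tighter (sd ~0.03) than real ABSOLUTE estimates, noise is independent
Gaussian with no gene-gene correlation, there are no batch effects, and
RNA-seq count properties (library size, overdispersion) are absent since
the model targets already-normalized z-scored matrices. Consequences:
clustering results on the default cohort are cleaner than on real data —
the four groups separate at the top level, whereas in real cohorts a
diluted subtype may only emerge on subclustering, and that merged scenario
is exercised separately. Passing tests on this cohort demonstrates the
machinery is correct, not that real cohorts of this size would classify
this cleanly. A wide-purity variant (Beta(7.7, 2.3) / Beta(6, 4)) is used
to study the relationship between dilution and ambiguous calls, where
low-purity samples drift toward the normal profile and lose their density
neighborhood.

`degrade_to_platform()` emulates cross-platform validation: a random gene
subset is retained (e.g. 161/168), each gene passes through a monotone
cubic distortion (`x + 0.15 x^3`) plus Gaussian noise (sd 0.3 on the
z-scale), and the result is re-standardized within the new "dataset" —
standardization is always within-dataset, never reusing training means.

## Numerical and convention choices

- Standardization uses the sample standard deviation (n-1); at cohort
  sizes in the hundreds the population/sample distinction is immaterial.
  Zero-variance genes become all-zero rows (kept, so signature indices
  stay aligned) and double standardization is an error.
- Probe collapse keeps, per gene, the probe with the highest mean
  intensity; ties break to the first probe in file order.
- DBSCAN clusters are numbered by discovery order, which together with
  canonicalized alignment makes consensus output invariant to any
  per-iteration label permutation, bit for bit.
- k-means for pattern groups reduces `k` with a warning when there are
  fewer distinct profiles than groups.
- Cox fits use Efron tie handling with a 1e-9 convergence tolerance.
- One master seed spawns per-stage sub-seeds (`derive_seeds`), so any
  stage can be re-run in isolation and reproduce the full-pipeline result;
  all sub-seeds stay below 2^31.

## Problem sizes used in the packaged analyses

The packaged analyses and validation runs use the 400-sample default
cohort with 100 DBU iterations of 500 genes, a 70-gene signature
(10 curated + 60 selected), and a 200-entry dictionary; the
purity-ambiguity analysis uses 250-sample wide-purity cohorts over
repeated seeds, and survival parameter recovery uses 2000-sample
survival-only cohorts. These sizes were chosen so the full suite runs
comfortably on a laptop while leaving every statistical check
well-powered; all of them scale up by changing the corresponding
configuration values.

## Known limitations

- The UMAP parameter grid search of the original workflow is not
  reproduced; its selected values are consumed as defaults.
- The moderated-statistic DE of a full differential-expression analysis is
  out of scope; the Welch t ranking is only a gene-selection device.
- Automated label alignment replaces a manual reorientation step; on data
  where iterations disagree wildly, the reference-selection heuristic (max
  mean ARI) may itself be unstable.
- `select_eps_knee()` is a reasonable initializer but noisier than a fixed
  radius chosen from pooled k-distance curves; the analyses fix eps.
- Hinge-loss SVMs (libsvm) stand behind the linear SVC wrapper; a
  squared-hinge primal solver would differ microscopically in weights but
  not in votes.
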