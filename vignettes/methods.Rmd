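---
title: "Methods: discovering characteristic rhizosphere bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering characteristic rhizosphere bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Plant varieties grown side by side under identical management can differ
markedly in product quality. One candidate explanation is below-ground:
varieties differ in which soil bacteria they recruit and accumulate in the
rhizosphere, those bacteria differ in how they transform soil nutrients,
and nutrient availability feeds into quality. `rhizotype` implements the
statistical workflow for testing this chain from a genus-level abundance
table: group the samples by their bacterial communities, find the genera
that drive the grouping, validate that those genera really discriminate,
and model the taxa → nutrients → quality cascade.

This vignette documents the models, the tunable parameters, the synthetic
data generator and the numerical choices, in enough detail to reimplement
every stage.

# Data model

The central container is the `abundance_table`: a non-negative matrix with
taxa as rows and samples as columns (the OTU-table convention) and a unit
flag, `counts` or `relative` (columns summing to 1 ± 1e-9). Readers accept
TSV/CSV in either orientation; negative cells, duplicate labels and
non-numeric entries are hard errors that name the offending cell. Sample
metadata is a plain data frame keyed by `sample_id` with optional group
labels, soil available N/P/K (mg/kg) and quality indexes (mg/kg); missing
fields are tolerated until an operation needs them, at which point the
error names the field.

Dominance ("genera above 1 %") is computed on the *mean relative
abundance across samples*, not on pooled counts, so samples sequenced more
deeply do not dominate the ranking; the threshold comparison is strict.

# Diversity estimators

* Shannon uses the natural logarithm. At several thousand taxa the
  observed index then falls in the high single digits, which is the scale
  soil 16S surveys report; a log2 variant would sit ~44 % higher.
* Simpson is reported as Gini–Simpson, `1 − Σ p²`, the variant that lies
  near 1 for diverse soils.
* Chao1 is `S_obs + F1²/(2 F2)` with the bias-corrected fallback
  `S_obs + F1(F1−1)/2` only when no doubletons exist. Chao1 requires
  integer counts and is `NA` on relative input; Shannon/Simpson accept
  both.
* The rarefaction curve is the exact hypergeometric expectation
  `E[S(d)] = Σ_i (1 − C(N−N_i, d)/C(N, d))`, evaluated with `lchoose` for
  numerical stability — no Monte Carlo. It is non-decreasing and concave
  in d (property-tested).
* The Shannon–depth curve and the species-accumulation curve are seeded
  Monte Carlo (without-replacement subsampling; random sample orderings).
* Bray–Curtis is computed on relative abundances by default so that
  sequencing-depth differences are not mistaken for community turnover;
  a `relative = FALSE` flag gives the counts version. Phylogenetic
  diversity is out of scope (no tree input).

# Grouping

`kmeans_groups()` z-scores the features and runs `stats::kmeans` with 25
random restarts, keeping the best inertia. We use the Hartigan–Wong
algorithm rather than plain Lloyd iterations: with a few dozen informative
genera among several hundred noisy dimensions, the planted partition is a
narrow optimum, and Hartigan–Wong's single-point reallocation step escapes
the local minima that trap Lloyd's batch updates (with either random or
k-means++ starts) in this regime. `k = "auto"` scans k = 2..8 and keeps
the maximum mean silhouette width; the study design this package targets
has k = 2, but the scan is cheap insurance.

Per-feature group tests default to Welch's t, falling back automatically
(with a message) to Mann–Whitney when a group has zero variance. The
Mann–Whitney p is computed by exact enumeration of rank-sum assignments
whenever both groups have ≤ 8 samples — this remains correct under ties,
which `wilcox.test`'s exact path refuses — and by the tie-corrected normal
approximation otherwise. P-values are Benjamini–Hochberg adjusted across
the feature batch.

# OPLS-DA

`fit_oplsda()` is a from-scratch Trygg–Wold orthogonal PLS-DA for two
classes:

1. X is autoscaled (unit variance; Pareto scaling by flag); y is coded
   +1/−1 and centered, so unbalanced groups are handled by the centering.
2. Orthogonal components are removed iteratively: with
   `w ∝ X'y`, `t = Xw`, `p = X't/t't`, the y-orthogonal loading is
   `w_o ∝ p − (w'p)w`; its score `t_o = X w_o` is deflated out of X.
   Deflation stops early if `‖w_o‖² < 1e-12` (no orthogonal variation
   left — a single-variable X degrades to plain PLS-DA with 0 orthogonal
   components).
3. One predictive NIPALS component is fitted on the filtered matrix.
   By construction the predictive score is exactly orthogonal to every
   orthogonal score (asserted to 1e-8 in the tests).

R²Y is in-sample (`1 − RSS/TSS`); Q² uses 7-fold venetian-blind
cross-validation (fold f holds out samples f, f+7, ...), with per-fold
re-centering on the globally scaled matrix. `n_ortho = "auto"` adds
orthogonal components while Q² improves by more than 0.01, up to 5.

VIP is computed on the predictive component,
`VIP_j = sqrt(p · w_j²/Σ w²)`, which yields the exact invariant
`mean(VIP²) = 1`; the conventional screen keeps VIP > 1. A total-VIP
variant across orthogonal components would break the invariant and is
deliberately not offered.

The permutation test refits the model on shuffled labels (the number of
orthogonal components resolved on the observed labels is held fixed across
permutations) and reports the add-one estimator
`p = (#{perm ≥ obs} + 1)/(n_perm + 1)`, so p can never be 0 and the
attainable minimum at 200 permutations is 1/201 ≈ 0.005. Test-suite
calibration (200 null datasets, 99 permutations each) checks the rejection
rate at the 5 % level stays within 0.05 ± 0.03.

Two cautions the test suite encodes: a single predictive component caps
R²Y at roughly `1/(1 + p_noise/n)` on data with one informative and many
autoscaled noise variables, so near-perfect R²Y on small n should not be
over-read; and null Q² at n = 40 occasionally reaches ≈ 0.2, so modest
positive Q² alone is weak evidence — hence the permutation test.

# Ensemble validation harness

`run_ensemble()` repeats, for i = 1..n_iterations with seed
`master_seed + i`: a stratified 80/20 split (per-class test counts are
`round(0.2 · n_class)`, minimum 1); per-split standardization using
training statistics; per family an inner stratified 5-fold grid search by
accuracy (first grid row wins ties); a refit of the winner on the full
training split; and recording of test predictions and class scores.
Pooling ("model integration") sums the confusion matrices and computes one
ROC/AUC per family from the concatenated score/label pairs; per-iteration
AUC averaging would discard cross-iteration calibration and is not the
default.

Default grids follow common practice: k = 1..20 for KNN; C and σ over
decades 1e-3..1e3 for the RBF-SVM; hidden size {2, 4, 8, 16} × weight
decay {0, 0.01, 0.1} for the single-hidden-layer network (logistic
activations, entropy loss, 500 epochs); 500 trees and mtry = 1..min(59, p)
for the forest; and a compact XGBoost grid over nrounds {50, 150},
max_depth {3, 6}, eta {0.1, 0.3}, colsample_bytree {0.6, 1},
min_child_weight {1, 5}, subsample {0.8, 1}. The pipeline preset trims
these grids and uses 25 iterations so a complete run stays in the minutes
range on one core; the full protocol is one `harness_config()` call away.

AUC uses the rank (Mann–Whitney) formulation with ties counted ½. SVM
scores are signed decision values passed through a logistic link so they
pool on the same [0, 1] scale as the probabilistic families.

One behavior worth knowing when constructing separability oracles:
XGBoost's exact greedy split places its threshold *at* the smallest
training value of the upper class, so a test point more extreme than every
same-class training point on the split feature lands on the wrong side no
matter how wide the class gap is. Perfect-AUC expectations therefore hold
on data whose class bands are discrete (test values coincide with training
values), and that is how the package's oracle tests construct them.

`feature_importance()` fits once on the full data — matching the single
published ranking per family — with fixed, documented hyperparameters
(forest: 500 trees, mtry = ⌊√p⌋, impurity importance; boosting: 150
rounds, depth 3, eta 0.1, total-gain importance; unused features score 0).
`top_n_intersection()` takes the top-30 of both rankings and returns the
shared features ordered by rank sum.

# Downstream analyses

* **RDA** (via `vegan::rda`) standardizes the responses (correlation RDA)
  because genus abundances and soil chemistry live on incommensurate
  scales; the headline number is the proportion of response variance the
  constraints explain, which is invariant to rotations of X.
* **Correlation network**: all pairwise Pearson r with two-sided
  t-approximation p, BH-adjusted within the batch; default gates
  |r| ≥ 0.6 and adjusted p ≤ 0.05, both configurable.
* **PLS-SEM** (`pls_sem()`) is a from-scratch Lohmöller estimator:
  mode A (correlation) outer weights, centroid inner scheme, iterated
  until the largest change in |outer weight| is below 1e-6 (max 300
  iterations, error with trace otherwise). Path coefficients are OLS of
  each endogenous latent on its predecessors; standard errors come from
  bootstrap resampling of samples (default 500) with normal-approximation
  p-values. The latent sign is fixed so the majority of loadings are
  positive; genera enriched in the *other* group simply load negatively,
  which is how the "bacterial load" construct accommodates
  opposite-direction taxa. With one indicator per block the latent equals
  the standardized indicator and path coefficients equal standardized
  regression slopes — the algebraic identity the tests exploit as an
  oracle.

# The synthetic data generator

`simulate_dataset()` emulates the statistical situation the analysis
assumes, at the published study's scale, and its defaults *are* those
conditions: 44 samples in groups of 31 and 13; 745 genera; 23
characteristic genera of which 19 are enriched in the larger group; a
log2 effect of 1.6; mean sequencing depth 50,000 (per-sample depths
Poisson); nutrient and quality phenotypes drawn inside the published
per-group ranges (e.g. available N 30.52–96.38 mg/kg in group A vs
20.19–40.08 in group B).

Counts are Dirichlet-multinomial: a power-law base profile
(`rank^-0.9`) mimics the steep rank–abundance curve of soil communities
and puts roughly 14–16 genera above the 1 % dominance line; per-sample
compositions are Dirichlet with total concentration `overdispersion`
around the group profile; characteristic genera have their base
proportions multiplied by `2^(±1.6)` in group A before renormalization.
Non-characteristic genera share one base profile across groups — a clean
null background for error-rate properties.

Two generator constants were calibrated once against the published
qualitative structure, before any acceptance test was written, and are
not revisited: the Dirichlet concentration (1000) and the abundance-rank
window characteristic genera are drawn from (ranks 5–150). At these values
the simulation reproduces what the study reports — an unambiguous
two-group K-means split, on the order of 190–200 genera passing VIP > 1
out of 745, and recoverable planted genera. The low overdispersion is
ecologically defensible here: each "sample" represents a composite of
five plants and three pooled replicates from one uniformly managed
nursery, which averages away much of the sample-to-sample compositional
noise a single soil core would show. Characteristic genera in the 5–150
rank window mirror the study, where several named characteristic genera
are also dominant (> 1 %) community members.

Phenotypes are chained, not parallel: nutrients are the group-range
midpoint plus `path_strength` times the standardized characteristic-taxon
load (enriched minus depleted relative abundance), scaled into the group
range, plus Gaussian noise of variance `1 − path_strength²`; quality is
the same function of the standardized nutrient load — quality depends on
taxa *only through* nutrients. This makes path-model recovery a meaningful
test: the taxa → nutrients and nutrients → quality coefficients are
planted positive at `path_strength = 0.8` and the direct taxa → quality
channel is absent. Note that because the per-group phenotype ranges differ
by construction, the *marginal* taxa–nutrient correlation does not vanish
as `path_strength → 0`; only the within-group correlation does, and that
is the invariant the tests check.

What the generator does **not** emulate: read-level artifacts (quality
trimming, chimeras, OTU clustering — the pipeline starts at the genus
table), phylogenetic structure, the 3-replicate nesting within varieties
(samples are exchangeable), taxon–taxon interaction networks in the null
background, and any direct taxa → quality effect. Passing recovery tests
therefore demonstrates that the statistical machinery finds the planted
structure under Dirichlet-multinomial noise — not that real communities
satisfy these assumptions.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes the stages in dependency order, persists each
completed stage as JSON before starting the next (a failing stage leaves
finished outputs on disk), and is byte-reproducible given the master seed:
stage seeds are fixed offsets of it, learner RNG flows from per-iteration
seeds, and JSON is written with sorted keys. `render_report()` turns a
bundle into a markdown summary and marks stages that did not run.

Problem sizes used by the shipped tests and acceptance script are chosen
to keep a complete run in the minutes range on a single core: the
full-scale simulated study (745 × 44) for recovery checks, repeated over
10 seeds; 200 null datasets at n = 20 for permutation calibration; 10–25
harness iterations with trimmed grids for the ensemble oracles; 500
bootstrap resamples for path significance. All of these are configuration,
not code limits.

# Known limitations

* Two-class OPLS-DA only; no multi-class extension or O2-PLS.
* Q² uses venetian-blind folds; leave-one-out or Monte Carlo CV are not
  offered.
* The VIP screen is marginal per-variable importance; correlated genera
  can pass or fail together, and the VIP > 1 count on null-heavy data
  includes chance passes (the intersection step exists precisely to prune
  them).
* PLS-SEM p-values use the normal approximation to the bootstrap, which
  is anticonservative for very small n; the tests bound the null
  rejection rate at ≤ 8 % rather than 5 %.
* RDA significance (axis permutation tests) is not implemented; the
  correlation network carries the significance calls instead.
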