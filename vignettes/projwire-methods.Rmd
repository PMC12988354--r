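---
title: "Models and methods behind projwire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind projwire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projwire)
```

# The problem

Barcoded retrograde viral tracing reads out the *projectome* of single
neurons: a retrograde vector carrying a target-specific barcode is injected
into each downstream nucleus, and the barcode UMI counts recovered in an
upstream neuron's transcriptome report which nuclei that neuron innervates,
and how strongly. Combined with single-cell expression profiles and spatial
coordinates, this yields a cells × targets UMI matrix, a cells × genes
expression matrix, and per-cell metadata — the three inputs `projwire`
consumes.

`projwire` covers the computational path from the raw barcode UMI matrix to:

1. background-filtered projection profiles (`filter_background`),
2. projection clusters and classes (`cluster_projections`),
3. binarized projection motifs and their enrichment against an independence
   null (`enumerate_motifs`, `motif_enrichment`),
4. target–target co-projection structure and its coupling to external
   circuit connectivity (`coprojection_matrix`, `block_contrast`,
   `coupling_correlation`),
5. spatial organization (`axis_binned_proportions`,
   `motif_distance_correlation`, `region_enrichment`),
6. gene co-expression modules, eigengenes and module–projection coupling
   (`correlation_network`, `detect_modules`, `module_eigengenes`,
   `module_projection_correlation`, `differential_expression`),
7. per-target projection prediction from transcriptome PCs plus spatial
   coordinates, with shuffle and ablation controls and cross-dataset
   transfer (`build_features`, `train_predictors`, `evaluate_roc`,
   `transfer_predict`, `compare_projection_maps`, `group_proportion_test`).

Every stage is validated against a synthetic-data generator
(`simulate_dataset`) that plants known classes, motifs, gradients and
modules, so recovery can be quantified exactly.

# Background filtering by elbow analysis

Ambient barcode molecules contaminate cells that do not project to a
barcode's target. For each target (after summing barcodes that share a
target), the positive UMI counts across cells are ranked in decreasing
order and plotted as $\bigl(i,\ \log_{10}(c_i + 1)\bigr)$. With ambient
contamination this curve has a characteristic shape: a signal head spanning
roughly $\log_{10} c \in [1, 3]$, then a corner, then a low shoulder of
ambient counts (1–3 UMIs).

`elbow_threshold` places the knee at the point of maximum perpendicular
distance to the chord joining the first and last points (ties resolved
toward the smaller rank, the stricter choice). Two geometric facts drive
the retention rule in `filter_background`:

* When an ambient shoulder exists, the knee lies **below** the chord, at
  the *top of the shoulder* — the largest ambient count, not the smallest
  signal count. Retention is therefore **strictly above** the knee count.
* When there is no ambient shoulder (pure signal, e.g. zero background),
  the maximum-distance point lies **above** the chord, on the bulge of the
  smooth count curve. Filtering there would cut into real signal, so an
  above-chord knee — or a knee count in the upper half of the log-count
  range — is treated as "no shoulder": all positive counts are retained.
  This makes the zero-background limit exact: with no ambient counts the
  filtered binary equals the true projection matrix.

Targets with fewer than three positive cells, or a flat count profile,
cannot be elbow-filtered and retain all positives with a report flag.

Under the synthetic regime used throughout (signal UMIs with mean 200 and
dispersion 2 over a Poisson(0.5) ambient rate), the filter reaches
cell–target sensitivity ≈ 0.999 and specificity ≈ 0.986: the knee lands on
the top ambient count (2), and counts ≥ 3 are overwhelmingly signal.

# The synthetic-data generator

`sim_config` / `simulate_dataset` generate a full multi-modal dataset with
ground truth. Per cell:

1. **Class.** Drawn from `class_mix` (default: four equi-probable classes
   named after the prefrontal projection taxonomy — an ipsilateral
   pyramidal-tract class and three intratelencephalic classes).
2. **Binary projections — Gaussian copula.** A latent normal vector over
   targets carries correlation `coupling_rho` between targets of the same
   class and 0 otherwise; thresholding at $\Phi^{-1}(p_{t,c})$ makes target
   $t$ fire with exactly its configured marginal. The copula was chosen
   because it decouples marginals from dependence: the motif null needs
   exact marginals at any coupling strength.
3. **UMI counts.** A fired cell–target pair draws
   $1 + \mathrm{NB}(\mu - 1, \theta)$ (a projection that was detected at
   all has at least one UMI); a silent pair draws
   $\mathrm{Poisson}(\lambda_{bg})$, the simplest model producing the
   low-count shoulder the elbow filter must cut. Real ambient
   contamination is likely cell-depth dependent; that refinement is
   deliberately out of scope and the filter is only claimed to work for
   shoulder-shaped backgrounds.
4. **Space.** `ap`/`dv` are class-specific normals (defaults spread over
   the 0.5–2.8 mm anterior–posterior and dorsoventral extent with 0.3 mm
   sd, placing the dorsal IT class dorsally and the ventral IT class
   ventrally); `ml` is uniform. Anatomical region labels (`ACC`, `MOs`,
   `PL`, `ILA`) are deterministic functions of position.
5. **Expression.** Each of `n_modules` gene modules has a per-cell score
   $s_m = \alpha_m z(\text{intensity of its coupled target}) +
   \sqrt{1 - \alpha_m^2}\,\varepsilon$; a module gene's log-normalized
   value is $\text{baseline} + \text{loading} \cdot s_m + N(0, \sigma)$,
   clipped at zero. Expression is emitted directly on the log-normalized
   layer — downstream stages consume normalized values, so count-level
   sampling would add machinery without adding a tested behavior.

**Class profiles.** Defaults are *anchor-structured*: four anchor targets
per class fired at 0.85, two secondary at 0.30, off-class at 0.01. Anchors
make same-class cells share most of their targets, which is what renders
classes geometrically recoverable; profiles with a uniform moderate
in-class probability make same-class cells fire nearly disjoint target
subsets, a regime in which *no* clustering of profiles can recover the
class partition (a likelihood-based check puts even the Bayes-optimal
accuracy well below what an ARI of 0.9 requires). The price is a
multi-target fraction (~0.96 under defaults) higher than real cortical
data, where roughly two thirds of labeled neurons are multi-target; the
generator prioritizes coherent, recoverable class structure over matching
that single statistic, and the multiplicity distribution should not be
read as a calibrated model of any real dataset.

`simulate_null_dataset` removes all structure (coupling 0, module coupling
0, shared spatial means, class-averaged marginals), so targets are
mutually independent Bernoulli draws — the reference condition for
calibration tests. `simulate_motif_mixture` plants a single enriched or
depleted pair motif whose probability is calibrated by exact enumeration
and root finding so that the achieved observed/expected ratio under the
*realized* marginals equals the requested value exactly.

# Projection clusters and classes

Cells are clustered on `log1p` of row-relative intensity: the relative
profile compares projection *pattern* rather than total UMI yield, and the
log tames the weight of single-target cells. One agglomerative tree is cut
at `n_clusters` (fine clusters) and `n_classes` (coarse classes), so
classes partition clusters by construction.

The default linkage is **Ward** (`ward.D2`). Average linkage — often the
first choice for sparse nonnegative profiles — fails structurally here: at
a coarse cut it peels off small outlier groups one by one, leaving one
giant cluster, and recovers essentially nothing of a planted 4-class
partition, while Ward recovers it at ARI > 0.9. Both linkage and metric
remain arguments.

# Motif enrichment against the independence null

All-zero rows are excluded: the motif universe is *labeled* neurons, and
marginals $p_t$ are column means over projecting cells. A motif with
target set $S$ has independence expectation
$E_S = N \prod_{t \in S} p_t \prod_{t \notin S} (1 - p_t)$, and each motif
observed at least `min_observed` (default 5, a floor for exact-test power
and table size) times is tested with the two-sided exact binomial test
(minimum-likelihood two-sided p, as implemented by `binom.test`), followed
by Benjamini–Hochberg correction and the over/under/not-significant call at
`q ≤ alpha`. Motifs whose expectation contains a structural marginal (0 or
1) are flagged degenerate and not tested.

One honest caveat: conditioning the universe on projecting cells makes
exact independence unattainable — if targets are independent *before*
conditioning, they are weakly negatively dependent after it, with
magnitude growing as the fraction of unlabeled cells grows (at six targets
with marginal 0.3 the induced pairwise phi reaches about −0.07). With the
marginals used in the calibration studies (0.15–0.5 over eight targets)
the effect is negligible and the empirical fraction of significant motifs
under the null stays well below the nominal level; with mostly-low
marginals it becomes detectable at $N = 5000$. Interpret enrichment
labels accordingly when most cells are unlabeled.

# Co-projection and wiring coupling

Co-projection is operationalized as the Pearson correlation of two
targets' binary columns over projecting cells — the phi coefficient of the
2×2 table. `block_contrast` symmetrizes any target-pair matrix, splits
upper-triangle entries into within-class and across-class sets and applies
a one-sided Wilcoxon rank-sum test (no distributional assumptions on phi
values; an all-tied input returns p = 1 by convention).
`coupling_correlation` symmetrizes a directed connectivity matrix by the
arithmetic mean — the plotted quantity in the source analyses is
"reciprocal" connection intensity, and the mean is the neutral reduction —
and correlates phi with connectivity across unordered target pairs,
excluding pairs with undefined phi.

# Co-expression modules and eigengenes

The module pipeline is deliberately parameter-light rather than a full
weighted-network topological-overlap stack: Pearson correlation across
cells, dissimilarity $1 - |r|$, average-linkage tree, cut at `k` modules
(`k = "auto"` maximizes the mean silhouette width over 2–10). Hubs are the
top genes by within-module sum of absolute adjacency. The module eigengene
is the first principal-component score of the module's gene-standardized
submatrix, rescaled to unit variance, sign-anchored to the module mean —
so an ME is always "expression-up means score-up".

Module–projection association is reported two ways, because the field's
figure legends name a correlation as the quantity but a Fisher test as the
significance procedure: `pearson_t` (Pearson r with t-test p) is the
default; `fisher_discrete` (ME dichotomized at its median × intensity
dichotomized at zero, two-sided Fisher's exact) is available, and both
agree in direction on strongly coupled planted modules. Differential
expression between projection groups uses linear-scale means (with a
$10^{-9}$ pseudo-rate) for the fold change and the Wilcoxon rank-sum test
per gene with BH correction.

# Projection prediction

Features are the top `n_pcs` principal components (default 50; the choice
is not critical on synthetic data and mirrors common scRNA practice) of
the gene-standardized log-normalized matrix, plus the three standardized
spatial coordinates. All standardization parameters and loadings are
stored, so the identical transform can be replayed on external data.

One gradient-boosted tree classifier per target (binary logistic
objective, depth-3 trees, learning rate 0.1, up to 300 rounds with early
stopping on an internal 20% validation fold, single-threaded for
determinism) is trained on a stratified 70/30 split; targets with fewer
than 10 training cells in either class are skipped and reported. Controls:

* **Shuffle** — test labels permuted against the same scores; AUC
  concentrates at 0.5 and its spread provides the chance band.
* **Spatial ablation** — the model retrained on the same split without
  coordinate columns; the AUC gap measures the spatial contribution. When
  only spatial signal is planted ($\alpha_m = 0$), the transcriptome-only
  model falls to chance while the full model stays above 0.9.

**Transfer** replaces anchor-based dataset integration (out of scope) with
deterministic shared-gene harmonization: the external matrix is restricted
to shared genes, standardized with *training* means/sds, missing genes
imputed at 0 (the training mean after standardization), projected through
the stored loadings, and scored by the trained models with binary calls at
probability 0.5. `compare_projection_maps` then compares region × target
projection percentages between predicted and reference datasets by Pearson
correlation; `group_proportion_test` compares, per target, the fraction of
activity-flagged cells among predicted projectors between two groups of
replicates with a two-sided t-test.

# Numerical conventions and degenerate inputs

* Tables are written with `.` decimals and 15 significant digits; a
  write–read round trip preserves values to ≥ 12 significant digits, and
  repeated runs of any CLI subcommand with the same seed are byte-stable.
* Relative normalization leaves all-zero rows at zero; `zscore_by_target`
  standardizes over projecting cells only.
* Constant columns (genes, targets, MEs) yield flagged `NA` results, never
  silent zeros, except where a contract defines the value (single-cluster
  z-scores are 0 with a flag).
* All simulation and training functions save and restore the global RNG
  state; the same `(config, seed)` is byte-reproducible.

# Problem sizes used in the validation suite

The packaged tests and the acceptance script run at the scales the
recovery properties were designed for: 5000 cells × 8 targets for filter
recovery, 50 replicates of 5000 cells for motif calibration and planted
motif detection (6 targets, baseline 0.3 — expected pair-motif count
~110, chosen so the exact test retains power for depletion against the
multiplicity correction), 3000 cells × 24 targets for class, module,
wiring, spatial and prediction recovery. These sizes put Monte-Carlo error
comfortably inside the asserted margins while keeping a full run in the
low minutes.

# Known limitations

* The generator does not model per-cell ambient load, dropout structure of
  imaging panels, slice geometry, or batch effects; passing recovery tests
  demonstrates correctness of the algorithms under the stated generative
  assumptions, not performance on any real dataset.
* The motif null is exactly correct only before conditioning on labeled
  cells (see above).
* The elbow filter assumes a shoulder-shaped ambient distribution; a
  background whose counts overlap the signal range will not produce a
  below-chord knee and will pass through unfiltered (by design, with a
  report flag).
* Phi between rarely-hit targets is noisy; `block_contrast` treats all
  pairs equally rather than weighting by marginal precision.
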