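# projwire

Analysis of single-cell **projectome–transcriptome** data from barcoded
retrograde viral tracing. A retrograde vector carrying a target-specific
barcode is injected into each downstream nucleus of a cortical area; the
barcode UMIs recovered in an upstream neuron then report which nuclei that
neuron innervates and how strongly. Together with the neuron's expression
profile and spatial position this yields three aligned matrices — cells ×
barcode UMIs, cells × genes, and per-cell metadata — and `projwire`
implements the full analysis path from those matrices to wiring statistics
and predictive models.

Intended users: systems-neuroscience and single-cell analysts working with
multiplexed retrograde barcode tracing (or simulated counterparts) in R.

## What it computes

| Stage | Model / statistic |
|---|---|
| Background filtering | Per-target knee of the ranked log-count curve: the point of maximal perpendicular distance to the chord; counts above a below-chord knee are signal, an above-chord knee means no ambient shoulder |
| Projection clusters / classes | Ward agglomerative clustering of log1p row-relative intensity, one tree cut at both granularities |
| Projection motifs | For motif set *S*: expected count *N* ∏<sub>t∈S</sub> p<sub>t</sub> ∏<sub>t∉S</sub>(1−p<sub>t</sub>) under target independence; two-sided exact binomial test, Benjamini–Hochberg FDR, over/under-representation calls |
| Co-projection | phi coefficient (Pearson on binary columns) per target pair; within- vs across-class Wilcoxon rank-sum; Pearson coupling with an external connectivity matrix |
| Spatial organization | Axis-binned per-target proportions with row z-scores; motif-pair spatial / transcriptome vs projection distance correlations |
| Co-expression modules | 1−\|r\| average-linkage modules (silhouette-selected k), intramodular-connectivity hubs, first-PC module eigengenes, ME × projection correlation (Pearson-t and discretized Fisher variants) |
| Prediction | Per-target gradient-boosted trees on expression PCs + (x, y, z), 70/30 stratified split, ROC/AUC with shuffle control and spatial-ablation control, shared-gene transfer to external spatial datasets |
| Synthetic data | Gaussian-copula projections with exact marginals, shifted-NB signal UMIs over Poisson ambient counts, class-specific spatial gradients, projection-coupled gene modules — with full planted truth |

## Worked example

```r
library(projwire)

cfg <- sim_config(n_cells = 2000)          # 24 targets, 4 projection classes
sim <- simulate_dataset(cfg, seed = 42)

prof <- filter_background(sim$dataset$barcode)
#> projection_profiles: 2000 cells x 24 targets; 1978 projecting cells
head(prof$report, 3)
#>   target_id cutoff n_positive n_retained filtered
#> 1     LHA-I      2       1077        497     TRUE
#> 2     VTA-I      2       1025        467     TRUE
#> 3      DR-I      2       1080        462     TRUE
```

The elbow filter finds the ambient shoulder of each target's ranked count
curve (cutoff 2: counts of 1–2 UMIs are ambient, ≥ 3 are signal), roughly
halving the positive calls per target.

```r
ms <- multiplicity_summary(prof)
#> multi-target fraction: 0.965 (max 13 targets)

cl <- cluster_projections(prof, n_clusters = 33, n_classes = 4)
table(cl$class_id)
#>   1   2   3   4
#> 495 488 465 530
```

Most neurons innervate several nuclei, and the class-level cut recovers
four balanced projection classes (ARI vs the planted classes > 0.9 at this
scale).

```r
tab <- motif_enrichment(prof$binary, alpha = 0.05)
head(tab[order(tab$q_value),
         c("signature", "observed", "expected", "q_value", "label")], 3)
#>                             signature observed expected   q_value           label
#> 6  CP-C+ACB-C+PL-C+AId-C+ECT-C+ENTl-C       62 0.000819 2.55e-276 overrepresented
#> 5  CP-I+RSP-I+VIS-I+AUD-I+SSp-I+MOs-I       64 0.001966 4.35e-262 overrepresented
#> 7 ACB-I+BLA-I+AId-I+ECT-I+ENTl-I+PL-I       55 0.001177 4.82e-234 overrepresented
```

The most over-represented motifs are the full within-class target sets —
cells hit all six targets of one class far more often than independent
marginals would allow, exactly the planted co-projection structure.

```r
cp <- coprojection_matrix(prof$binary)
bc <- block_contrast(cp$phi,
                     setNames(default_targets()$class_id,
                              default_targets()$target_id))
#> within-class phi median 0.47 vs across -0.14 (rank-sum p = 1.12e-32)
```

See the methods vignette (`vignettes/projwire-methods.Rmd`) for the models,
parameter choices and limitations, and `?simulate_dataset`,
`?motif_enrichment`, `?train_predictors` for the interfaces.

## Command line

```sh
Rscript inst/cli/projwire.R simulate --config sim.yaml --seed 7 --out out/
Rscript inst/cli/projwire.R motifs   --config ds.yaml  --seed 7 --out out/
```

Subcommands: `simulate filter cluster motifs coproject spatial modules
predict`; each reads a YAML config, writes TSV/JSON results plus a log with
version, seed and input checksums, and is byte-stable for a fixed seed.

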