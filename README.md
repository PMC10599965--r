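# smoothscore

Per-cell gene set scoring on neighbor-graph-smoothed single-cell counts.

Single-sample gene set scoring reduces each expression profile to one number
per signature — a B-cell identity score, an inflammatory-response score — so
that downstream statistics can work with cells instead of genes. Applied
directly to scRNA-seq counts these scores are fragile: the data are shallow
and sparse, most genes tie at zero or one count, and rank-based statistics
are unstable under such ties. `smoothscore` addresses this the way
pseudobulk analyses do, but without giving up single-cell resolution: each
cell's profile is replaced by a weighted combination of itself and its K
nearest transcriptomic neighbors before scoring.

The pipeline, per annotation group (so information is never shared across
cell types, samples, or conditions):

1. **Group** cells by user-chosen annotation columns (`groupby`).
2. **Embed** each group (median-depth normalization, `log1p`, per-gene
   scaling, PCA) and build an exact K-nearest-neighbor graph.
3. **Weight** edges with a density-adjusted Gaussian kernel,
   `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` with `sigma_i` the distance
   from cell *i* to its K-th neighbor, symmetrized by the elementwise
   maximum; or use a binary adjacency, or the identity (smoothing off).
4. **Smooth** by sparse multiplication `M = A X`, where `X` is the cells ×
   genes count matrix and `A` the adjacency operator.
5. **Score** every cell of `M` against each gene set with one of eight
   single-sample statistics: `singscore`, `ssgsea`, `rank_biased_overlap`,
   `mean_z_score`, `average_score`, `median_score`, `summed_up`,
   `geneset_overlap`. Two-part signatures (an up half and a down half, read
   from `.up`/`.dn` suffixed GMT pairs) are scored in opposition.

A negative-binomial simulator with a planted marker signature, binomial
count thinning, and a Mann–Whitney AUC utility support end-to-end
validation without any external download.

## Worked example

```r
library(smoothscore)

sim <- simulate_two_populations(
  n_cells_a = 1000, n_cells_b = 1000, n_genes = 1000,
  marker_genes = 40, fold_change = 1.5, dispersion = 2, seed = 1)
ds  <- sim$dataset          # 2000 cells x 1000 genes, sparse counts
lab <- ds$annotations$population

unsmoothed <- score_cells(ds, sim$markers, method = "summed_up",
                          smooth_mode = "off", groupby = "population")
smoothed   <- score_cells(ds, sim$markers, method = "summed_up",
                          smooth_mode = "connectivity", knn = 32,
                          groupby = "population")

auc_separation(unsmoothed$markers__summed_up, lab, positive = "B")
#> [1] 0.860939
auc_separation(smoothed$markers__summed_up, lab, positive = "B")
#> [1] 1
```

The 40 marker genes are elevated 1.5-fold in population B. Scoring the raw
counts separates the populations imperfectly (AUC 0.86): at ~0.5 counts per
gene per cell the signature genes are mostly tied at zero. After smoothing
over each cell's 32 nearest neighbors — graphs built separately within each
population, mirroring how real analyses group by cell type or sample — the
summed-rank score separates the populations perfectly (AUC 1.0).

The robustness of the smoothed score to sequencing depth:

```r
rc <- run_robustness_curve(ds, sim$markers,
                           fractions = c(0.95, 0.5, 0.2, 0.1, 0.05),
                           k_values = c(0L, 32L),
                           groupby = "population", seed = 1)
autoplot(rc)
```

At 10% of the original counts the unsmoothed AUC has fallen to ~0.67 while
the K = 32 smoothed score still scores ~1.0.

Everything is also available from a shell:

```sh
inst/exec/smoothscore simulate --out-dir fixture --seed 1
inst/exec/smoothscore score \
  --counts fixture/matrix.mtx --genes fixture/genes.txt \
  --cells fixture/cells.txt --annotations fixture/annotations.tsv \
  --gmt fixture/markers.gmt --out scores.tsv \
  --method singscore --groupby population --knn 32
inst/exec/smoothscore overlap --knn-grid 0,8,32 ... # K-selection diagnostic
```

Every run writes a JSON report of all effective parameters, per-group sizes
and K used, and gene set coverages.

## Vignette

`vignettes/smoothed-geneset-scoring.Rmd` documents the model and its
assumptions, every scoring function's exact definition, the kernel and
normalization choices, what the simulator does and does not emulate, and
known limitations.
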