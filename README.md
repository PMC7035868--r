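# celldeck

Interactive exploration of processed single-cell RNA-seq data needs three
things that upstream pipelines do not provide: a single self-describing file
format that any collaborator can open, the interactive computations behind
the plots (filtering, manual group selection, on-the-fly differential
expression, dot-plot summaries), and a way to reach datasets wherever they
live — a laptop folder, an HTTP server, an S3 bucket. **celldeck** is an R
toolkit providing exactly that backend: it converts CellRanger output, loom
files and raw text tables into a validated AnnData-layout HDF5 (h5ad)
container, and exposes every computation an exploration front-end needs,
both as ordinary R functions and over a lightweight JSON/TSV web service.
It is aimed at bioinformatics core units and method developers who hand
processed single-cell data to collaborators without computational
background.

## What it computes

- **Container.** Cells × genes UMI counts plus a normalized layer
  (per-cell scaling to 10,000 counts, then log(1 + x)), per-cell and
  per-gene annotation, named 2-D embeddings (t-SNE/UMAP), a marker-gene
  table, and markdown metadata. Stored as h5ad; files interoperate with
  the scanpy/anndata ecosystem in both directions.
- **Selection.** Conjunctive cell filters over categorical columns,
  inclusive numeric ranges, and box/lasso regions on embeddings
  (boundary-inclusive even–odd ray casting for point-in-polygon tests).
- **Differential expression.** For two disjoint cell groups A and B and
  each gene *g* with expression vectors *x*, *y* on the normalized layer,
  the two-sided Wilcoxon rank-sum test (exact null when
  *n*<sub>A</sub>+*n*<sub>B</sub> ≤ 12 without ties, otherwise the
  tie-corrected normal approximation without continuity correction),
  Benjamini–Hochberg adjustment over the tested genes, and
  log<sub>2</sub>FC = log<sub>2</sub>((μ<sub>A</sub>+ε)/(μ<sub>B</sub>+ε))
  on de-logged group means (ε = 10⁻⁹). Genes expressed in less than 10 %
  of cells in both groups are excluded before testing.
- **Summaries.** Dot-plot statistics (mean expression over all group
  cells and fraction of cells expressing, optionally split by condition),
  cluster-composition tables, per-group distribution quartiles, barnyard
  species-mix doublet calling, and reproducible scatter downsampling.
- **Synthetic data.** Negative-binomial clustered datasets with planted
  marker genes, two-species UMI mixtures with a known doublet rate, and
  on-disk CellRanger/loom/text fixtures — so every computation is testable
  against ground truth without external downloads.

## Worked example

```r
library(celldeck)

sim <- generate_clustered_dataset(sim_spec(n_cells = 200, n_genes = 200,
                                           k_clusters = 2, fold_change = 4,
                                           condition_fraction = 0.5, seed = 42))
ds <- sim$dataset
ds
#> <cell_dataset> Synthetic clustered dataset (seed 42)
#>   200 cells x 200 genes (counts: present)
#>   cell columns: cell_id, cluster, n_counts, condition
#>   embeddings: tsne
#>   markers: 20 rows

save_dataset(ds, "pbmc-like.h5ad")   # readable by scanpy/anndata too

groups <- assign_groups(list(A = which(ds$cell_table$cluster == "1"),
                             B = which(ds$cell_table$cluster == "2")))
res <- differential_expression(ds, groups)
res
#> differential expression A (n=100) vs B (n=100): 200 genes tested, 0 skipped
#>     symbol statistic         p     p_adj log2fc mean_a mean_b frac_a frac_b
#> 1  GENE007      8936 4.586e-22 9.171e-20  2.435  4.850  2.430   0.96   0.64
#> 2  GENE003      8772 2.762e-20 2.705e-18  2.019  4.818  3.039   0.96   0.78
#> 3  GENE011      1246 4.057e-20 2.705e-18 -2.108  2.834  4.917   0.73   0.98
#> ...
```

The top genes are exactly the planted cluster markers: `GENE001`–`GENE010`
were simulated 4-fold up in cluster 1 and `GENE011`–`GENE020` in cluster 2,
so positive log2FC rows are cluster-1 markers and negative rows cluster-2
markers, with BH-adjusted p-values far below any reasonable cutoff.
A split dot plot summarizes them per cluster and condition:

```r
dot_plot_summary(ds, res$symbol[1:2], "cluster", split_by = "condition")
#>      gene group split mean fraction
#> 1 GENE007     1  ctrl 4.90    0.958
#> 2 GENE007     1  stim 4.81    0.962
#> 3 GENE007     2  ctrl 2.71    0.706
#> 4 GENE007     2  stim 2.14    0.571
#> ...
```

`mean` is the average normalized expression over **all** cells of the
group (zeros included); `fraction` is the share of cells with a positive
value — the two numbers a dot plot encodes as color and size.

### Converting real data and serving it

```sh
inst/cli/celldeck convert /path/to/cellranger/outs/filtered_feature_bc_matrix out.h5ad
inst/cli/celldeck run --data-source /data/h5ad-folder --port 8050
```

`run` serves a JSON/TSV API (catalog, about, filter, diffexp, dotplot,
composition, distribution, scatter, upload — see `?run_server`) whose
payloads are byte-identical to the corresponding library calls. Data
sources may be local paths or `http(s)://`, `ftp://`, `sftp://`,
`s3://` URLs (also via the `CELLDECK_DATA_SOURCES` environment variable);
remote files are cached by canonical URL.

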