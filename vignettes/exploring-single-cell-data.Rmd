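---
title: "Models and methods behind celldeck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind celldeck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldeck)
```

celldeck is the computational backend of an interactive single-cell
explorer: it stores processed scRNA-seq data in one validated container,
selects cells, compares groups, and summarizes expression for plotting.
This vignette documents the models and procedures, the parameters that
matter, the numerical choices, and the limits of what the test suite
demonstrates.

## The container and its normalized layer

A `cell_dataset` holds a cells × genes UMI count matrix, a normalized
layer, per-cell and per-gene tables, named 2-D embeddings, an optional
marker table and markdown metadata. All summaries and differential
expression operate on the **normalized layer**; counts are retained for
bit-exact archival and re-processing.

The normalization is the dominant convention of the single-cell
ecosystem: each cell is scaled to a fixed target of 10,000 total counts
and transformed with $\log(1 + x)$. The target (argument `target_sum`,
default 10,000) is a display convention, not a statistical claim; it makes
values comparable across cells of different sequencing depth and keeps
files interchangeable with datasets prepared by other tools. Cells with
zero total counts are left at zero rather than producing non-finite
values. Some inputs carry only processed expression (no raw counts); the
container accepts that, marking counts as absent, and conversely derives
the normalized layer when only counts are given. When loading a foreign
h5ad whose `X` holds only whole numbers and no counts layer exists, `X`
is interpreted as raw counts — the most common way such files are
produced — and the normalized layer is derived; files written by this
package always store both layers explicitly, so the heuristic never
applies to them.

On disk the container is an AnnData-layout HDF5 file: normalized
expression in `X` (CSR sparse; CSC and dense are accepted on read), raw
counts under `layers/counts`, tables in `obs`/`var` with categorical
columns stored as integer codes plus category strings, embeddings under
`obsm/X_<name>`, markers and metadata under `uns`. Element-level
encoding attributes follow the AnnData on-disk dialect, so files written
here open unchanged in Python's anndata/scanpy and vice versa. Round-trip
fidelity is part of the tested contract: counts bit-exact, normalized
values within $10^{-12}$, tables, embeddings, markers and metadata equal.

Indices on the library surface are 1-based throughout, following R
convention; translating to the 0-based codes of the on-disk format is
the persistence layer's job, not the caller's. This is a deliberate
deviation from the habits of Python-based relatives of this design: a
0-based surface inside R would force error-prone off-by-one translation
at every call site.

## Converters

CellRanger's filtered feature-barcode matrix (Matrix Market triplets plus
barcode and feature TSVs, plain or gzipped) is transposed from gene-major
to cells × genes. Features not typed `Gene Expression` are dropped with a
warning, because mixed-modality matrices would violate the container's
single-assay contract. If an `analysis` folder is present, the
conventional CellRanger paths (`clustering/graphclust/clusters.csv`,
`<method>/2_components/projection.csv`,
`diffexp/graphclust/differential_expression.csv`) are tried first and a
single glob match is accepted otherwise; two or more candidates raise an
error rather than guessing. From the CellRanger differential-expression
table, rows with adjusted p < 0.05 and positive log2 fold change become
the marker table.

Loom files are read with the loom convention of a genes × cells main
matrix; row attributes become the gene table, column attributes the cell
table, and numeric column-attribute pairs `<name>_X`/`<name>_Y`
(case-insensitive suffix) are reassembled into embedding `<name>`.
Unpaired suffixed columns stay ordinary columns.

Raw text input is a delimited gene × cell matrix (symbol in the first
column) plus a per-cell annotation table. The delimiter is sniffed from
the first line (tab preferred, comma fallback). Cells are aligned by
identifier: the intersection is kept in matrix order and every dropped
cell is counted in the conversion report. Annotation columns are typed
by a stated, overridable heuristic: non-numeric columns become factors,
and numeric columns with at most `max_factor_levels` (default 20)
distinct values are treated as cluster-like and also become factors.
The default deliberately errs toward categorical: cluster labels stored
as integers are far more common in such files than 20-level numeric
covariates, and the parameter exists precisely because small datasets
can make genuinely numeric columns look discrete. Duplicate gene symbols
are made unique with `.1`, `.2` suffixes and reported.

## Remote sources, caching, catalogs

Dataset locators cover `file`, `http(s)`, `ftp`, `sftp` and `s3`.
Credentials embedded in a URL are captured at parse time and stripped
from the canonical rendered form, which is the only form that appears in
error messages, logs and cache keys. The `irods` scheme is recognized
but deliberately raises a not-implemented error: supporting it would
require a service dependency that cannot be exercised on a desk, and a
stub that fails loudly is more honest than silent misbehavior. Remote
fetches are cached under a SHA-256 hash of the canonical URL and never
revalidated — in this workflow datasets are immutable artifacts, so
cache invalidation machinery (ETags, TTLs) would add failure modes
without adding value. Catalog listing enumerates `.h5ad` files directly
contained in a local folder, lexicographically; remote folder listing is
out of scope because no protocol in the supported set offers a reliable,
uniform directory listing.

## Selection geometry

Filters are conjunctions of predicates: categorical membership,
inclusive numeric ranges, and regions on an embedding. All boundaries
are inclusive — a cell exactly on the edge of a box or polygon counts as
selected, matching what users expect of a box-select gesture. Point-in-
polygon membership uses even–odd ray casting with an explicit
on-boundary test (cross-product within $10^{-12}$ of zero, scaled by the
polygon's coordinate magnitude). The tests compare it against an
independently formulated winding-number oracle on random convex
polygons, where the two definitions provably coincide; for
self-intersecting lasso paths the even–odd rule is the behavior users
see in mainstream plotting front-ends.

Manually selected groups may overlap (two lasso gestures can cover the
same cells). Overlapping cells are removed from *all* groups rather than
assigned to the first or last selection, because any order-dependent rule
would make downstream differential expression depend on click order; the
overlap count is reported as a warning.

## Differential expression

The two-group comparison is the Wilcoxon rank-sum test on the normalized
layer, the dominant convention for two-group scRNA-seq comparisons: it is
distribution-free, robust to the zero inflation of UMI data, and
verifiable on a desk against exact enumeration. With pooled sample size
at most 12 and no ties the exact null distribution is used; otherwise
the normal approximation with tie-corrected variance and no continuity
correction. A comparison with zero rank variance (all values tied)
returns p = 1. P-values are clamped to (0, 1].

Genes expressed (stored value > 0) in less than `min_fraction_expressed`
(default 0.1) of the cells of *both* groups are excluded before testing.
This pre-filter is part of the procedure: the Benjamini–Hochberg step-up
adjustment uses $m$ = number of genes actually tested, and the untested
count is reported alongside the results. Each group must contain at
least `min_cells_per_group` cells (default 3; the test itself needs 2) —
below that, rank-sum p-values are meaningless and the error says which
group is too small.

The reported fold change is
$\log_2\!\bigl((\mu_A + \varepsilon)/(\mu_B + \varepsilon)\bigr)$ where
$\mu$ are group means of $e^{x}-1$ (the de-logged normalized values) and
$\varepsilon = 10^{-9}$ (configurable) regularizes all-zero groups.
Result rows are ordered by ascending p, ties by descending
$|\log_2\text{FC}|$, then symbol, making output deterministic down to
byte-identical TSV serialization.

## Summaries

Dot-plot statistics report, per gene and group (optionally subdivided by
a second condition column — the split dot plot used for
stimulated-versus-control comparisons), the mean normalized expression
over **all** cells of the group including zeros, and the fraction of
cells with a positive stored value. The inclusive mean is a documented
choice: it is what the color scale of the split-dot-plot style this
follows encodes, and it keeps mean × fraction interpretable as total
expression mass. Group/condition combinations with no cells are omitted
rather than zero-filled, so plots do not show fabricated zeros.

Composition tables count a secondary categorical within each level of a
primary one; declared levels with zero cells are retained with count 0,
and proportions of an empty level are reported as 0 with an explicit
`defined = FALSE` flag rather than NaN. Distribution panels report
per-group quartiles with linear interpolation (R's default type 7),
fixed so that other implementations can reproduce the numbers exactly.
Species-mixing statistics call a cell a singlet when one species owns at
least `purity_threshold` (default 0.9) of its UMIs and a doublet
otherwise; 0.9 is a conventional operating point for modern barnyard
data where ambient contamination sits near 1 %, and it is configurable
because older chemistries are noisier. Scatter downsampling is a uniform
sample without replacement, seeded explicitly and isolated from the
caller's RNG state.

Every summary accepts an optional cell subset and is tested to agree
exactly with the same summary computed on a physically subset dataset —
the property that makes filter-then-summarize pipelines trustworthy.

## Synthetic data: what it does and does not emulate

The generator exists so that every computation can be tested against
planted ground truth without external downloads. Counts are negative
binomial — mean `baseline_mean` (default 2 UMIs per gene), size
parameter `dispersion` (default 2, i.e. variance $\mu + \mu^2/2$) —
capturing the overdispersion that makes Poisson simulations too easy for
rank-based tests. Cells are assigned to `k_clusters` round-robin; each
cluster's planted marker genes (default 10 per cluster) have their mean
multiplied by `fold_change` (default 4) in that cluster. The default
study condition of 100 cells per group at 4-fold effect is the regime
where a rank-sum test should recover essentially all planted markers,
and the tests assert exactly that, as well as the complementary null:
at `fold_change = 1` the p-value distribution is uniform to within
binomial error.

The 2-D "tsne" embedding is *not* a manifold embedding: cluster
centroids sit on a circle of radius 10 with unit Gaussian spread. The
explorer only needs coordinates with visible cluster structure; no
geometric claim is made. Species mixtures draw singlets 1:1, own-species
counts Poisson(`mean_umis`, default 1000) with 1 % ambient
contamination from the other species, and doublets as sums of two
opposite-species singlets, with the doublet count binomial in
`doublet_rate`.

Consequently, passing tests demonstrate correctness of the *procedures*
— rank computations, multiple-testing adjustment, selection geometry,
round-trip persistence — under a clean generative model. They do not
demonstrate robustness to batch effects, cell-cycle structure, ambient
RNA within one species, or realistic embedding geometry, none of which
the generator attempts to simulate.

## The service layer

The web service adds no computation: each route parses its JSON body,
calls the corresponding library function, and serializes with the same
TSV/JSON helpers a direct caller would use, so payloads are byte-equal
to library output — a property the test suite asserts over live HTTP.
Datasets load lazily on first access; sources that fail to parse are
reported in the catalog rather than aborting startup. Uploads (off by
default) are validated before being cataloged. The command-line
interface (`inst/cli/celldeck`) is a thin wrapper over `cli_convert()`
and `run_server()`.

## Problem sizes in the test suite

The suite and acceptance script run on simulated datasets of 30–200
cells and 40–200 genes, 25 round-trip replicates, 100 rank-sum oracle
pairs, 1,000 BH vectors, 50 random polygons × 200 points, and 10
species-mix replicates of 1,000 cells — sizes chosen so the full suite
exercises every code path, including exact-test branches and HTTP round
trips, while remaining a coffee-break run on a laptop.

## Known limitations

- Single-assay expression only: no CITE-seq/ATAC modalities, no backed
  (out-of-core) matrices; files are loaded whole.
- No pseudobulk, covariate-adjusted or mixed-model differential
  expression, and no gene-set enrichment.
- Legacy AnnData dialects that store `obs`/`var` as HDF5 compound tables
  (pre-0.8 writers) are not read.
- Folder catalogs are local-only and shallow; remote catalogs need an
  explicit file list.
- `irods://` locators are recognized but unimplemented by design.
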