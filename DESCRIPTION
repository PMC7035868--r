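Package: celldeck
Title: Convert, Store and Interactively Explore Processed Single-Cell
    RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for turning processed single-cell RNA-seq
    results into a self-describing AnnData-layout HDF5 (h5ad) container and
    exploring it interactively. Converts 10X Genomics CellRanger output,
    loom files and raw delimited text; resolves datasets from local folders
    or remote sources (HTTP(S), FTP, SFTP, S3); filters cells by categorical,
    numeric-range and embedding-region criteria; runs on-the-fly two-group
    Wilcoxon differential expression with Benjamini-Hochberg correction;
    computes plot-ready dot-plot, composition, distribution and species-mix
    summaries; and serves everything over a lightweight JSON/TSV web service
    with a matching command-line interface. Includes a synthetic-data module
    that generates clustered expression datasets with planted markers,
    species-mixing UMI tables, and on-disk CellRanger/loom/text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    curl,
    digest,
    httpuv,
    jsonlite,
    methods,
    rhdf5,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
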