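# Synthetic data: clustered expression datasets with planted marker genes,
# two-species UMI mixtures with a known doublet rate, and on-disk
# CellRanger / loom / text fixtures. All generators are pure functions of
# their specification and seed.

#' Specification for a synthetic clustered dataset
#'
#' Defaults describe a small but realistic desk-scale test dataset:
#' 2 clusters of 100 cells each, 200 genes of which 10 per cluster are
#' planted markers at a 4-fold effect, negative-binomial counts with a
#' baseline mean of 2 UMIs per gene and moderate overdispersion
#' (`dispersion` is the NB size parameter: variance = mu + mu^2/size).
#'
#' @param n_cells,n_genes,k_clusters Dataset dimensions.
#' @param de_genes_per_cluster Planted marker genes per cluster.
#' @param fold_change Multiplicative effect (> 1) of a planted gene in its
#'   cluster.
#' @param baseline_mean Baseline NB mean per gene and cell.
#' @param dispersion NB size (inverse-dispersion) parameter.
#' @param condition_fraction Optional fraction in (0, 1); when set, a
#'   two-level `condition` column ("ctrl"/"stim") is drawn per cell with
#'   this probability of "stim".
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(n_cells = 200L, n_genes = 200L, k_clusters = 2L,
                     de_genes_per_cluster = 10L, fold_change = 4,
                     baseline_mean = 2, dispersion = 2,
                     condition_fraction = NULL, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
               k_clusters = as.integer(k_clusters),
               de_genes_per_cluster = as.integer(de_genes_per_cluster),
               fold_change = fold_change, baseline_mean = baseline_mean,
               dispersion = dispersion,
               condition_fraction = condition_fraction,
               seed = as.integer(seed))
  if (spec$n_cells < spec$k_clusters) {
    cd_stop("celldeck_spec_error", "need n_cells >= k_clusters")
  }
  if (spec$de_genes_per_cluster * spec$k_clusters > spec$n_genes) {
    cd_stop("celldeck_spec_error",
            "de_genes_per_cluster * k_clusters must not exceed n_genes")
  }
  if (spec$fold_change < 1 || spec$baseline_mean <= 0 ||
      spec$dispersion <= 0) {
    cd_stop("celldeck_spec_error",
            "fold_change >= 1, baseline_mean > 0 and dispersion > 0 required")
  }
  if (!is.null(spec$condition_fraction) &&
      (spec$condition_fraction <= 0 || spec$condition_fraction >= 1)) {
    cd_stop("celldeck_spec_error", "condition_fraction must be in (0, 1)")
  }
  structure(spec, class = "sim_spec")
}

#' Generate a clustered synthetic dataset with planted markers
#'
#' Cells are assigned to clusters round-robin. Counts are negative binomial
#' with mean `baseline_mean`, multiplied by `fold_change` for each
#' cluster's planted genes in that cluster's cells. A 2-D "tsne" embedding
#' places each cluster at a centroid on a circle of radius 10 with unit
#' Gaussian spread around it -- deliberately not a real manifold embedding,
#' just visibly separated coordinates. The marker table is filled from the
#' planted ground truth.
#'
#' @param spec A [sim_spec()].
#' @return `list(dataset = cell_dataset, ground_truth = list(clusters,
#'   marker_genes))` where `marker_genes` maps cluster label -> planted
#'   symbols.
#' @export
generate_clustered_dataset <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    g <- spec$n_genes
    k <- spec$k_clusters
    cluster <- factor(rep_len(seq_len(k), n))
    symbols <- sprintf("GENE%03d", seq_len(g))
    planted <- lapply(seq_len(k), function(j) {
      idx <- ((j - 1L) * spec$de_genes_per_cluster + 1L):
        (j * spec$de_genes_per_cluster)
      symbols[idx]
    })
    names(planted) <- levels(cluster)

    mu <- matrix(spec$baseline_mean, nrow = n, ncol = g)
    for (j in seq_len(k)) {
      in_cluster <- cluster == levels(cluster)[j]
      gene_idx <- match(planted[[j]], symbols)
      mu[in_cluster, gene_idx] <- mu[in_cluster, gene_idx] * spec$fold_change
    }
    counts <- matrix(stats::rnbinom(n * g, mu = as.vector(mu),
                                    size = spec$dispersion),
                     nrow = n, ncol = g)

    angle <- 2 * pi * (seq_len(k) - 1L) / k
    centroids <- cbind(10 * cos(angle), 10 * sin(angle))
    coords <- centroids[as.integer(cluster), , drop = FALSE] +
      matrix(stats::rnorm(2L * n), ncol = 2L)

    cell_table <- data.frame(
      cell_id = sprintf("cell%04d", seq_len(n)),
      cluster = cluster,
      n_counts = as.numeric(rowSums(counts)),
      stringsAsFactors = FALSE)
    if (!is.null(spec$condition_fraction)) {
      cell_table$condition <- factor(
        ifelse(stats::runif(n) < spec$condition_fraction, "stim", "ctrl"),
        levels = c("ctrl", "stim"))
    }
    gene_table <- data.frame(
      gene_id = sprintf("SYNT%05d", seq_len(g)),
      symbol = symbols, stringsAsFactors = FALSE)
    markers <- data.frame(
      cluster = rep(names(planted), each = spec$de_genes_per_cluster),
      gene = unlist(planted, use.names = FALSE),
      log2fc = log2(spec$fold_change), stringsAsFactors = FALSE)
    if (spec$de_genes_per_cluster == 0L) {
      markers <- NULL
    }
    ds <- cell_dataset(
      counts = counts, cell_table = cell_table, gene_table = gene_table,
      embeddings = list(tsne = coords), markers = markers,
      about = list(
        title = sprintf("Synthetic clustered dataset (seed %d)", spec$seed),
        short = sprintf("%d cells, %d genes, %d clusters", n, g, k),
        long = paste("Simulated negative-binomial UMI counts with planted",
                     "cluster markers; for testing and illustration.")),
      cluster_column = "cluster")
    list(dataset = ds,
         ground_truth = list(clusters = cluster, marker_genes = planted))
  })
}

#' Simulate a two-species (barnyard) UMI mixture
#'
#' Singlets are assigned to the two species 1:1 at random; their own-species
#' UMI counts are Poisson(`mean_umis`) with Poisson(0.01 * `mean_umis`)
#' ambient contamination from the other species. Each doublet is the sum of
#' two independent singlets of opposite species. The number of doublets is
#' binomial(`n_cells`, `doublet_rate`).
#'
#' @param n_cells Number of cells.
#' @param doublet_rate True doublet probability in \[0, 1).
#' @param mean_umis Mean own-species UMI count of a singlet.
#' @param seed Integer seed.
#' @return Data frame with per-cell columns `h`, `m`, `true_call`
#'   (`species1` / `species2` / `doublet`).
#' @export
generate_species_mix <- function(n_cells, doublet_rate = 0.02,
                                 mean_umis = 1000, seed = 1L) {
  if (mean_umis <= 0) {
    cd_stop("celldeck_spec_error", "mean_umis must be > 0")
  }
  if (doublet_rate < 0 || doublet_rate >= 1) {
    cd_stop("celldeck_spec_error", "doublet_rate must be in [0, 1)")
  }
  with_seed(seed, {
    ambient <- 0.01 * mean_umis
    is_doublet <- stats::runif(n_cells) < doublet_rate
    species1 <- stats::runif(n_cells) < 0.5
    own <- stats::rpois(n_cells, mean_umis)
    amb <- stats::rpois(n_cells, ambient)
    h <- ifelse(species1, own, amb)
    m <- ifelse(species1, amb, own)
    # doublets: add an independent singlet of the opposite species
    extra_own <- stats::rpois(n_cells, mean_umis)
    extra_amb <- stats::rpois(n_cells, ambient)
    h <- h + ifelse(is_doublet, ifelse(species1, extra_amb, extra_own), 0)
    m <- m + ifelse(is_doublet, ifelse(species1, extra_own, extra_amb), 0)
    data.frame(
      h = as.integer(h), m = as.integer(m),
      true_call = factor(ifelse(is_doublet, "doublet",
                                ifelse(species1, "species1", "species2")),
                         levels = c("species1", "species2", "doublet")),
      stringsAsFactors = FALSE)
  })
}

#' Write a CellRanger-style fixture directory
#'
#' Emits `matrix.mtx` (gene-major Matrix Market), `barcodes.tsv` and
#' `features.tsv` (optionally gzipped) such that [convert_cellranger()]
#' reproduces the counts bit-exact.
#'
#' @param ds A `cell_dataset` with counts.
#' @param directory Output directory (created).
#' @param gzip Write gzipped files.
#' @return Invisibly, `directory`.
#' @export
write_cellranger_fixture <- function(ds, directory, gzip = FALSE) {
  if (is.null(ds$counts) || n_cells(ds) == 0L || n_genes(ds) == 0L) {
    cd_stop("celldeck_spec_error",
            "refusing to write a fixture for an empty or counts-free dataset")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  pathify <- function(base) {
    file.path(directory, if (gzip) paste0(base, ".gz") else base)
  }
  mtx_plain <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(Matrix::t(ds$counts), mtx_plain)  # genes x cells
  if (gzip) {
    con <- gzfile(pathify("matrix.mtx"), "w")
    writeLines(readLines(mtx_plain), con)
    close(con)
    unlink(mtx_plain)
  }
  write_lines_maybe_gz <- function(lines, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
  }
  write_lines_maybe_gz(ds$cell_table$cell_id, pathify("barcodes.tsv"))
  write_lines_maybe_gz(
    paste(ds$gene_table$gene_id, ds$gene_table$symbol, "Gene Expression",
          sep = "\t"),
    pathify("features.tsv"))
  invisible(directory)
}

#' Write a loom fixture file
#'
#' Main matrix genes x cells (loom convention), `col_attrs/CellID` plus the
#' cell-table columns, `row_attrs/Gene` and `row_attrs/Accession`, and
#' embeddings as `<name>_X`/`<name>_Y` column attributes, as consumed by
#' [convert_loom()].
#'
#' @param ds A `cell_dataset` with counts.
#' @param file Output loom path.
#' @return Invisibly, `file`.
#' @export
write_loom_fixture <- function(ds, file) {
  if (is.null(ds$counts) || n_cells(ds) == 0L || n_genes(ds) == 0L) {
    cd_stop("celldeck_spec_error",
            "refusing to write a fixture for an empty or counts-free dataset")
  }
  if (file.exists(file)) unlink(file)
  fid <- rhdf5::H5Fcreate(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  # R (cells, genes) appears to C-order loom readers as (genes, cells)
  rhdf5::h5write(as.matrix(ds$counts), fid, "matrix")
  rhdf5::h5createGroup(fid, "row_attrs")
  rhdf5::h5createGroup(fid, "col_attrs")
  rhdf5::h5createGroup(fid, "layers")
  rhdf5::h5write(ds$gene_table$symbol, fid, "row_attrs/Gene",
                 variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5write(ds$gene_table$gene_id, fid, "row_attrs/Accession",
                 variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5write(ds$cell_table$cell_id, fid, "col_attrs/CellID",
                 variableLengthString = TRUE, encoding = "UTF-8")
  for (col in setdiff(names(ds$cell_table), "cell_id")) {
    v <- ds$cell_table[[col]]
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) {
      rhdf5::h5write(v, fid, paste0("col_attrs/", col),
                     variableLengthString = TRUE, encoding = "UTF-8")
    } else {
      rhdf5::h5write(as.numeric(v), fid, paste0("col_attrs/", col))
    }
  }
  for (nm in names(ds$embeddings)) {
    e <- ds$embeddings[[nm]]
    rhdf5::h5write(e[, 1], fid, paste0("col_attrs/", nm, "_X"))
    rhdf5::h5write(e[, 2], fid, paste0("col_attrs/", nm, "_Y"))
  }
  h5_attr(fid, "LOOM_SPEC_VERSION", "3.0.0", scalar = TRUE)
  invisible(file)
}

#' Write a delimited-text fixture (matrix + annotation)
#'
#' The matrix file holds gene rows x cell columns with the symbol in the
#' first column; the annotation file one row per cell with the identifier
#' first, cell-table columns, and embeddings as `<name>_X`/`<name>_Y`
#' columns, as consumed by [convert_text()].
#'
#' @param ds A `cell_dataset` with counts.
#' @param matrix_file,annotation_file Output paths.
#' @param sep Field separator (tab default; comma also supported).
#' @return Invisibly, `matrix_file`.
#' @export
write_text_fixture <- function(ds, matrix_file, annotation_file,
                               sep = "\t") {
  if (is.null(ds$counts) || n_cells(ds) == 0L || n_genes(ds) == 0L) {
    cd_stop("celldeck_spec_error",
            "refusing to write a fixture for an empty or counts-free dataset")
  }
  m <- t(as.matrix(ds$counts))  # genes x cells
  mtab <- data.frame(symbol = ds$gene_table$symbol, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  names(mtab) <- c("symbol", ds$cell_table$cell_id)
  utils::write.table(mtab, matrix_file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  atab <- data.frame(cell_id = ds$cell_table$cell_id,
                     stringsAsFactors = FALSE)
  for (col in setdiff(names(ds$cell_table), "cell_id")) {
    v <- ds$cell_table[[col]]
    atab[[col]] <- if (is.factor(v)) as.character(v) else v
  }
  for (nm in names(ds$embeddings)) {
    atab[[paste0(nm, "_X")]] <- ds$embeddings[[nm]][, 1]
    atab[[paste0(nm, "_Y")]] <- ds$embeddings[[nm]][, 2]
  }
  utils::write.table(atab, annotation_file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_file)
}
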