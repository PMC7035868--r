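# Converters: CellRanger output, loom files and raw delimited text ->
# cell_dataset. Each returns list(dataset = <cell_dataset>,
# report = <conversion_report>).

conversion_report <- function(n_cells, n_genes, warnings, source_format) {
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 warnings = as.character(warnings),
                 source_format = source_format),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("conversion (%s): %d cells x %d genes\n", x$source_format,
              x$n_cells, x$n_genes))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# first existing candidate among plain and gzipped variants, else NA
find_input_file <- function(directory, candidates) {
  for (base in candidates) {
    for (f in c(file.path(directory, base), file.path(directory,
                                                      paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
  }
  NA_character_
}

# read a possibly-gzipped text table without headers
read_tsv_plain <- function(path, sep = "\t") {
  utils::read.table(path, sep = sep, header = FALSE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}

# Matrix::readMM needs a plain file; decompress .gz inputs to a tempfile
read_mtx <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp))
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  Matrix::readMM(path)
}

# de-duplicate gene symbols with ".1", ".2" suffixes; returns list with
# symbols and warning messages
dedupe_symbols <- function(symbols) {
  dup <- unique(symbols[duplicated(symbols)])
  out <- make.unique(symbols, sep = ".")
  warnings <- if (length(dup)) {
    sprintf("de-duplicated %d repeated gene symbol(s): %s", length(dup),
            paste(utils::head(dup, 5L), collapse = ", "))
  } else character()
  list(symbols = out, warnings = warnings)
}

# resolve a CellRanger analysis CSV: preferred conventional path first, then
# a glob; two or more glob matches is an error, never a guess
resolve_analysis_csv <- function(directory, preferred, pattern) {
  p <- file.path(directory, preferred)
  if (file.exists(p)) return(p)
  hits <- Sys.glob(file.path(directory, pattern))
  if (length(hits) > 1L) {
    cd_stop("celldeck_format_error",
            "ambiguous analysis files (%d match %s); keep only one",
            length(hits), pattern)
  }
  if (length(hits) == 1L) hits else NA_character_
}

#' Convert a CellRanger output directory
#'
#' Reads the filtered feature-barcode matrix (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv` or legacy `genes.tsv`, each optionally gzipped), transposes
#' the gene-major Matrix Market triplets to cells x genes, drops non-"Gene
#' Expression" features with a warning, and derives the normalized layer.
#' If an `analysis` subdirectory exists, its clustering CSV becomes a
#' categorical `cluster` column, its t-SNE/UMAP projection CSVs become
#' embeddings, and its differential-expression CSV becomes the marker table
#' (rows with adjusted p < 0.05 and positive log2 fold change).
#'
#' @param directory CellRanger output directory.
#' @param about Optional list with `title`, `short`, `long`.
#' @return `list(dataset = cell_dataset, report = conversion_report)`.
#' @export
convert_cellranger <- function(directory, about = NULL) {
  if (!dir.exists(directory)) {
    cd_stop("celldeck_io_error", "no such directory: %s", directory)
  }
  warnings <- character()
  mtx <- find_input_file(directory, "matrix.mtx")
  bc <- find_input_file(directory, "barcodes.tsv")
  ft <- find_input_file(directory, c("features.tsv", "genes.tsv"))
  missing <- c("matrix.mtx", "barcodes.tsv", "features.tsv/genes.tsv")[
    is.na(c(mtx, bc, ft))]
  if (length(missing)) {
    cd_stop("celldeck_format_error", "missing CellRanger input file(s): %s",
            paste(missing, collapse = ", "))
  }
  m <- read_mtx(mtx)  # genes x cells
  barcodes <- read_tsv_plain(bc)[[1]]
  features <- read_tsv_plain(ft)
  if (nrow(m) != nrow(features) || ncol(m) != length(barcodes)) {
    cd_stop("celldeck_format_error",
            "matrix header (%d genes x %d cells) does not match %d features / %d barcodes",
            nrow(m), ncol(m), nrow(features), length(barcodes))
  }
  if (ncol(features) >= 3L) {
    keep <- features[[3]] == "Gene Expression"
    if (!all(keep)) {
      warnings <- c(warnings, sprintf(
        "dropped %d non-'Gene Expression' feature(s)", sum(!keep)))
      features <- features[keep, , drop = FALSE]
      m <- m[keep, , drop = FALSE]
    }
  }
  counts <- Matrix::t(m)  # cells x genes
  dd <- dedupe_symbols(as.character(features[[min(2L, ncol(features))]]))
  warnings <- c(warnings, dd$warnings)
  cell_table <- data.frame(cell_id = as.character(barcodes),
                           stringsAsFactors = FALSE)
  gene_table <- data.frame(gene_id = as.character(features[[1]]),
                           symbol = dd$symbols, stringsAsFactors = FALSE)

  embeddings <- list()
  markers <- NULL
  analysis <- file.path(directory, "analysis")
  if (dir.exists(analysis)) {
    cl <- resolve_analysis_csv(analysis, "clustering/graphclust/clusters.csv",
                               "clustering/*/clusters.csv")
    if (!is.na(cl)) {
      tab <- utils::read.csv(cl, stringsAsFactors = FALSE)
      idx <- match(cell_table$cell_id, tab[[1]])
      cell_table$cluster <- factor(tab[[2]][idx])
    }
    for (method in c("tsne", "umap")) {
      pr <- resolve_analysis_csv(analysis,
                                 file.path(method, "2_components",
                                           "projection.csv"),
                                 file.path(method, "*", "projection.csv"))
      if (!is.na(pr)) {
        tab <- utils::read.csv(pr, stringsAsFactors = FALSE)
        idx <- match(cell_table$cell_id, tab[[1]])
        embeddings[[method]] <- as.matrix(tab[idx, 2:3])
      }
    }
    de <- resolve_analysis_csv(analysis,
                               "diffexp/graphclust/differential_expression.csv",
                               "diffexp/*/differential_expression.csv")
    if (!is.na(de)) {
      markers <- parse_cellranger_diffexp(de, gene_table)
    }
  }
  ds <- cell_dataset(counts = counts, cell_table = cell_table,
                     gene_table = gene_table, embeddings = embeddings,
                     markers = markers,
                     about = dataset_about(about, basename(directory)))
  assert_valid_dataset(ds)
  list(dataset = ds,
       report = conversion_report(n_cells(ds), n_genes(ds), warnings,
                                  "cellranger"))
}

# CellRanger differential_expression.csv: Feature ID, Feature Name, then per
# cluster a (mean counts, log2 fold change, adjusted p) column triplet.
# Rows with adjusted p < 0.05 and positive fold change become markers.
parse_cellranger_diffexp <- function(path, gene_table) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) return(NULL)
  triplets <- seq(3L, ncol(tab) - 2L, by = 3L)
  rows <- list()
  for (start in triplets) {
    cl <- sub("^Cluster ([0-9]+) .*$", "\\1", names(tab)[start])
    lfc <- tab[[start + 1L]]
    padj <- tab[[start + 2L]]
    keep <- is.finite(lfc) & is.finite(padj) & padj < 0.05 & lfc > 0
    if (!any(keep)) next
    sym <- gene_table$symbol[match(tab[[1]][keep], gene_table$gene_id)]
    sym[is.na(sym)] <- as.character(tab[[2]][keep])[is.na(sym)]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, gene = sym, log2fc = lfc[keep], p_adj = padj[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Convert a loom file
#'
#' The loom main matrix is genes x cells; it is transposed to cells x genes.
#' Row attributes become the gene table, column attributes the cell table,
#' and column-attribute pairs named `<name>_X`/`<name>_Y` (case-insensitive)
#' are assembled into embedding `<name>`. Integer-valued matrices are taken
#' as raw counts (normalized layer derived); anything else is stored as the
#' normalized layer directly.
#'
#' @param file Path to a loom (HDF5) file.
#' @param about Optional list with `title`, `short`, `long`.
#' @return `list(dataset = cell_dataset, report = conversion_report)`.
#' @export
convert_loom <- function(file, about = NULL) {
  if (!file.exists(file)) {
    cd_stop("celldeck_io_error", "no such file: %s", file)
  }
  if (!isTRUE(rhdf5::H5Fis_hdf5(file))) {
    cd_stop("celldeck_format_error", "not an HDF5/loom file: %s", file)
  }
  ls_tab <- rhdf5::h5ls(file)
  full <- ifelse(ls_tab$group == "/", paste0("/", ls_tab$name),
                 paste(ls_tab$group, ls_tab$name, sep = "/"))
  if (!"/matrix" %in% full) {
    cd_stop("celldeck_format_error", "loom file lacks a main /matrix")
  }
  # C-order (genes, cells) on disk -> rhdf5 yields (cells, genes)
  m <- rhdf5::h5read(file, "/matrix")
  m <- as_dgc(m)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    cd_stop("celldeck_format_error", "empty dataset: loom matrix is %d x %d",
            ncol(m), nrow(m))
  }
  read_attrs <- function(group, n_expected) {
    out <- list()
    for (nm in ls_tab$name[ls_tab$group == group]) {
      v <- as.vector(rhdf5::h5read(file, paste0(group, "/", nm)))
      if (length(v) == n_expected) out[[nm]] <- v
    }
    out
  }
  row_attrs <- read_attrs("/row_attrs", ncol(m))  # per gene
  col_attrs <- read_attrs("/col_attrs", nrow(m))  # per cell

  pick <- function(attrs, candidates) {
    hit <- intersect(candidates, names(attrs))
    if (length(hit)) as.character(attrs[[hit[1]]]) else NULL
  }
  symbol <- pick(row_attrs, c("Gene", "gene", "GeneName", "var_names",
                              "symbol"))
  if (is.null(symbol)) symbol <- sprintf("gene%d", seq_len(ncol(m)))
  gene_id <- pick(row_attrs, c("Accession", "gene_id"))
  dd <- dedupe_symbols(symbol)
  warnings <- dd$warnings
  gene_table <- data.frame(gene_id = if (is.null(gene_id)) dd$symbols else gene_id,
                           symbol = dd$symbols, stringsAsFactors = FALSE)
  for (nm in setdiff(names(row_attrs),
                     c("Gene", "gene", "GeneName", "var_names", "symbol",
                       "Accession", "gene_id"))) {
    gene_table[[nm]] <- row_attrs[[nm]]
  }

  cell_id <- pick(col_attrs, c("CellID", "cell_id", "obs_names", "barcode"))
  if (is.null(cell_id)) cell_id <- sprintf("cell%d", seq_len(nrow(m)))
  id_names <- c("CellID", "cell_id", "obs_names", "barcode")
  rest <- col_attrs[setdiff(names(col_attrs), id_names)]
  emb <- pair_embedding_columns(rest)
  cell_table <- data.frame(cell_id = cell_id, stringsAsFactors = FALSE)
  for (nm in names(emb$columns)) {
    v <- emb$columns[[nm]]
    cell_table[[nm]] <- if (is.character(v)) factor(v) else v
  }
  if (is_count_matrix(m)) {
    counts <- m
    normalized <- NULL
  } else {
    counts <- NULL
    normalized <- m
  }
  ds <- cell_dataset(counts = counts, normalized = normalized,
                     cell_table = cell_table, gene_table = gene_table,
                     embeddings = emb$embeddings,
                     about = dataset_about(about,
                                           sub("\\.loom$", "",
                                               basename(file))))
  assert_valid_dataset(ds)
  list(dataset = ds,
       report = conversion_report(n_cells(ds), n_genes(ds), warnings, "loom"))
}

# pull `<name>_X`/`<name>_Y` pairs (case-insensitive suffix) out of a named
# list of per-cell vectors; unpaired suffixed columns stay plain columns
pair_embedding_columns <- function(columns) {
  embeddings <- list()
  used <- character()
  nms <- names(columns)
  is_x <- grepl("_[Xx]$", nms)
  for (nm in nms[is_x]) {
    base <- substr(nm, 1L, nchar(nm) - 2L)
    partner <- nms[tolower(nms) == tolower(paste0(base, "_y"))]
    if (length(partner) == 1L && is.numeric(columns[[nm]]) &&
        is.numeric(columns[[partner]])) {
      embeddings[[base]] <- cbind(as.numeric(columns[[nm]]),
                                  as.numeric(columns[[partner]]))
      used <- c(used, nm, partner)
    }
  }
  list(embeddings = embeddings, columns = columns[setdiff(nms, used)])
}

#' Convert raw delimited text tables
#'
#' `matrix_file` holds gene rows x cell columns with the gene symbol in the
#' first column; `annotation_file` has one row per cell with the cell
#' identifier in the first column. The delimiter (tab or comma) is sniffed
#' from the first line of each file. Cells are aligned by identifier: the
#' intersection is kept in matrix order and dropped cells are counted in the
#' report warnings. Non-numeric annotation columns become factors, as do
#' numeric columns with at most `max_factor_levels` distinct values
#' (cluster-like); columns named `<name>_X`/`<name>_Y` become embeddings.
#'
#' @param matrix_file Delimited expression matrix (plain or gzip).
#' @param annotation_file Delimited per-cell annotation (plain or gzip).
#' @param about Optional list with `title`, `short`, `long`.
#' @param max_factor_levels Numeric columns with at most this many distinct
#'   values are treated as categorical (default 20).
#' @return `list(dataset = cell_dataset, report = conversion_report)`.
#' @export
convert_text <- function(matrix_file, annotation_file, about = NULL,
                         max_factor_levels = 20L) {
  for (f in c(matrix_file, annotation_file)) {
    if (!file.exists(f)) cd_stop("celldeck_io_error", "no such file: %s", f)
  }
  sniff <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
  }
  warnings <- character()
  mtab <- utils::read.table(matrix_file, sep = sniff(matrix_file),
                            header = TRUE, quote = "", comment.char = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
  atab <- utils::read.table(annotation_file, sep = sniff(annotation_file),
                            header = TRUE, quote = "", comment.char = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
  symbols <- as.character(mtab[[1]])
  cells_m <- names(mtab)[-1]
  cells_a <- as.character(atab[[1]])
  common <- intersect(cells_m, cells_a)
  if (!length(common)) {
    cd_stop("celldeck_format_error",
            "no overlapping cell identifiers between matrix and annotation")
  }
  dropped <- (length(cells_m) - length(common)) +
    (length(cells_a) - length(common))
  if (dropped > 0L) {
    warnings <- c(warnings, sprintf(
      "dropped %d cell(s) present in only one file", dropped))
  }
  keep <- cells_m[cells_m %in% common]  # matrix order
  mat <- t(as.matrix(mtab[, keep, drop = FALSE]))  # cells x genes
  storage.mode(mat) <- "double"
  dd <- dedupe_symbols(symbols)
  warnings <- c(warnings, dd$warnings)

  atab <- atab[match(keep, cells_a), , drop = FALSE]
  ann <- atab[, -1, drop = FALSE]
  typed <- lapply(names(ann), function(nm) {
    v <- ann[[nm]]
    if (is.numeric(v)) as.numeric(v) else suppressWarnings({
      num <- as.numeric(v)
      if (!anyNA(num)) num else as.character(v)
    })
  })
  names(typed) <- names(ann)
  emb <- pair_embedding_columns(typed)
  cell_table <- data.frame(cell_id = keep, stringsAsFactors = FALSE)
  for (nm in names(emb$columns)) {
    v <- emb$columns[[nm]]
    if (is.character(v)) {
      cell_table[[nm]] <- factor(v)
    } else if (length(unique(v)) <= max_factor_levels) {
      cell_table[[nm]] <- factor(v)  # cluster-like numeric annotation
    } else {
      cell_table[[nm]] <- v
    }
  }
  gene_table <- data.frame(gene_id = dd$symbols, symbol = dd$symbols,
                           stringsAsFactors = FALSE)
  if (is_count_matrix(mat)) {
    counts <- mat; normalized <- NULL
  } else {
    counts <- NULL; normalized <- mat
  }
  ds <- cell_dataset(counts = counts, normalized = normalized,
                     cell_table = cell_table, gene_table = gene_table,
                     embeddings = emb$embeddings,
                     about = dataset_about(about,
                                           sub("\\.[^.]*$", "",
                                               basename(matrix_file))))
  assert_valid_dataset(ds)
  list(dataset = ds,
       report = conversion_report(n_cells(ds), n_genes(ds), warnings, "text"))
}
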