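#' Annotated single-cell expression container
#'
#' `cell_dataset()` bundles everything the explorer needs for one dataset:
#' a UMI count matrix, a depth-normalized log expression layer, per-cell and
#' per-gene annotation tables, named 2-D embeddings, an optional marker-gene
#' table and free-text metadata. It is the contract every other module
#' consumes; [validate_dataset()] checks its invariants and
#' [save_dataset()] / [load_dataset_file()] persist it as an AnnData-layout
#' HDF5 (h5ad) file.
#'
#' @details
#' Matrices are cells x genes. `counts` holds non-negative integer UMI
#' counts and may be `NULL` when the input provided only processed values;
#' `normalized` is the layer all summaries and differential expression use.
#' When only counts are given, `normalized` is derived by per-cell scaling
#' to 10,000 total counts followed by `log1p` (see [normalize_counts()]).
#'
#' `cell_table` must contain a `cell_id` column with unique identifiers;
#' other columns are either factors (categorical annotation such as cluster
#' or condition) or numeric (per-cell statistics such as sequencing depth).
#' `gene_table` must contain unique `gene_id` and unique `symbol` columns.
#' All cell and gene indices on the library surface are 1-based.
#'
#' @param counts Optional cells x genes matrix of UMI counts (dense or
#'   sparse; stored as `dgCMatrix`).
#' @param normalized Optional cells x genes matrix of normalized log
#'   expression. Derived from `counts` when omitted.
#' @param cell_table Data frame of per-cell annotation incl. `cell_id`.
#' @param gene_table Data frame of per-gene annotation incl. `gene_id` and
#'   `symbol`.
#' @param embeddings Named list of cells x 2 numeric matrices (e.g.
#'   `tsne`, `umap`).
#' @param markers Optional marker-gene data frame with at least columns
#'   `cluster` and `gene`; score columns (`p`, `p_adj`, `log2fc`, `score`)
#'   are schema-flexible because upstream pipelines differ.
#' @param about List with `title`, `short`, `long` (markdown) describing the
#'   dataset.
#' @param cluster_column Name of the cell-table column that marker cluster
#'   labels refer to, or `NULL` if none is designated.
#'
#' @return An object of class `cell_dataset`.
#' @seealso [validate_dataset()], [save_dataset()], [load_dataset_file()]
#' @export
#' @examples
#' counts <- matrix(c(1, 0, 0, 2, 3, 0), nrow = 3, byrow = TRUE)
#' ds <- cell_dataset(
#'   counts = counts,
#'   cell_table = data.frame(cell_id = c("c1", "c2", "c3")),
#'   gene_table = data.frame(gene_id = c("g1", "g2"),
#'                           symbol = c("ACTB", "GAPDH"))
#' )
#' validate_dataset(ds)
cell_dataset <- function(counts = NULL, normalized = NULL, cell_table,
                         gene_table, embeddings = list(), markers = NULL,
                         about = NULL, cluster_column = NULL) {
  if (is.null(counts) && is.null(normalized)) {
    cd_stop("celldeck_spec_error",
            "at least one of 'counts' and 'normalized' is required")
  }
  if (!is.null(counts)) {
    counts <- as_dgc(counts)
  }
  if (is.null(normalized)) {
    normalized <- normalize_counts(counts)
  } else {
    normalized <- as_dgc(normalized)
  }
  cell_table <- as.data.frame(cell_table, stringsAsFactors = FALSE)
  gene_table <- as.data.frame(gene_table, stringsAsFactors = FALSE)
  rownames(cell_table) <- NULL
  rownames(gene_table) <- NULL
  embeddings <- lapply(embeddings, function(e) {
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    dimnames(e) <- NULL
    e
  })
  if (is.null(markers)) {
    markers <- data.frame(cluster = character(), gene = character(),
                          stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
    rownames(markers) <- NULL
    if ("cluster" %in% names(markers)) {
      markers$cluster <- as.character(markers$cluster)
    }
  }
  about <- dataset_about(about)
  if (is.null(cluster_column) && "cluster" %in% names(cell_table)) {
    cluster_column <- "cluster"
  }
  dimnames(normalized) <- NULL
  if (!is.null(counts)) dimnames(counts) <- NULL
  structure(
    list(counts = counts, normalized = normalized, cell_table = cell_table,
         gene_table = gene_table, embeddings = embeddings, markers = markers,
         about = about, cluster_column = cluster_column),
    class = "cell_dataset"
  )
}

# normalize about metadata to a complete title/short/long list
dataset_about <- function(about, default_title = "Untitled dataset") {
  if (is.null(about)) about <- list()
  list(
    title = if (is_string(about$title)) about$title else default_title,
    short = if (is_string(about$short)) about$short else "",
    long = if (is_string(about$long)) about$long else ""
  )
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales each cell to 10,000 total counts, then applies `log1p`. This is
#' the de-facto convention of the scanpy/Seurat ecosystem, which keeps
#' datasets produced here interoperable with files produced there. Cells
#' with zero total counts are left at zero.
#'
#' @param counts Cells x genes count matrix (dense or sparse).
#' @param target_sum Per-cell total after scaling (default 10,000).
#' @return A sparse `dgCMatrix` of normalized log expression.
#' @export
normalize_counts <- function(counts, target_sum = 1e4) {
  counts <- as_dgc(counts)
  totals <- Matrix::rowSums(counts)
  scale <- ifelse(totals > 0, target_sum / totals, 0)
  out <- Matrix::Diagonal(x = scale) %*% counts
  out <- methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- NULL
  out
}

#' Number of cells / genes in a dataset
#' @param ds A `cell_dataset`.
#' @return Integer count.
#' @export
n_cells <- function(ds) nrow(ds$normalized)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$normalized)

#' Validate a dataset against its invariants
#'
#' Checks every structural rule of the container: matching matrix and table
#' shapes, two-column embeddings with one row per cell, unique cell
#' identifiers and gene symbols, non-negative integer counts, finite
#' non-negative normalized values, and marker cluster labels that exist in
#' the designated clustering column. Validation reports; it never raises.
#'
#' @param ds A `cell_dataset`.
#' @return Character vector of violation descriptions; empty if the dataset
#'   is well-formed. Each violation names the field and the rule broken.
#' @export
validate_dataset <- function(ds) {
  v <- character()
  add <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))
  if (!inherits(ds, "cell_dataset")) {
    return("object: not a cell_dataset")
  }
  nc <- nrow(ds$normalized)
  ng <- ncol(ds$normalized)
  if (!is.null(ds$counts)) {
    if (!identical(dim(ds$counts), dim(ds$normalized))) {
      add("counts: shape %d x %d differs from normalized %d x %d",
          nrow(ds$counts), ncol(ds$counts), nc, ng)
    }
    if (!is_count_matrix(ds$counts)) {
      add("counts: entries must be non-negative integers")
    }
  }
  x <- ds$normalized@x
  if (length(x) && (!all(is.finite(x)) || any(x < 0))) {
    add("normalized: entries must be finite and >= 0")
  }
  if (nrow(ds$cell_table) != nc) {
    add("cell_table: %d rows but %d cells", nrow(ds$cell_table), nc)
  }
  if (nrow(ds$gene_table) != ng) {
    add("gene_table: %d rows but %d genes", nrow(ds$gene_table), ng)
  }
  if (!"cell_id" %in% names(ds$cell_table)) {
    add("cell_table: missing cell_id column")
  } else if (anyDuplicated(ds$cell_table$cell_id)) {
    add("cell_table: cell_id values are not unique")
  }
  for (col in c("gene_id", "symbol")) {
    if (!col %in% names(ds$gene_table)) {
      add("gene_table: missing %s column", col)
    } else if (anyDuplicated(ds$gene_table[[col]])) {
      add("gene_table: %s values are not unique", col)
    }
  }
  for (col in names(ds$cell_table)) {
    val <- ds$cell_table[[col]]
    if (!is.factor(val) && !is.numeric(val) && !is.character(val)) {
      add("cell_table: column %s is neither categorical nor numeric", col)
    }
  }
  if (length(ds$embeddings)) {
    if (is.null(names(ds$embeddings)) || any(names(ds$embeddings) == "")) {
      add("embeddings: all embeddings must be named")
    }
    for (nm in names(ds$embeddings)) {
      e <- ds$embeddings[[nm]]
      if (!is.matrix(e) || ncol(e) != 2L) {
        add("embeddings: '%s' must have exactly 2 columns (has %s)",
            nm, if (is.matrix(e)) ncol(e) else "no dims")
      } else if (nrow(e) != nc) {
        add("embeddings: '%s' has %d rows but %d cells", nm, nrow(e), nc)
      } else if (!all(is.finite(e))) {
        add("embeddings: '%s' contains non-finite coordinates", nm)
      }
    }
  }
  if (nrow(ds$markers)) {
    need <- setdiff(c("cluster", "gene"), names(ds$markers))
    if (length(need)) {
      add("markers: missing mandatory column(s) %s",
          paste(need, collapse = ", "))
    } else if (!is.null(ds$cluster_column)) {
      if (!ds$cluster_column %in% names(ds$cell_table)) {
        add("markers: designated cluster column '%s' not in cell_table",
            ds$cluster_column)
      } else {
        levs <- ds$cell_table[[ds$cluster_column]]
        levs <- if (is.factor(levs)) levels(levs) else unique(as.character(levs))
        bad <- setdiff(unique(as.character(ds$markers$cluster)), levs)
        if (length(bad)) {
          add("markers: cluster label(s) %s not levels of '%s'",
              paste(bad, collapse = ", "), ds$cluster_column)
        }
      }
    }
  }
  v
}

# raise a classed error when a dataset is invalid
assert_valid_dataset <- function(ds) {
  v <- validate_dataset(ds)
  if (length(v)) {
    cd_stop("celldeck_validation_error", "invalid dataset:\n  %s",
            paste(v, collapse = "\n  "))
  }
  invisible(ds)
}

#' Compare two datasets under the equality contract
#'
#' Counts are compared bit-exact, normalized values within `tol`, tables,
#' embeddings, markers and about must be equal. Categorical columns are
#' compared on their values; with `strict_levels = TRUE` the stored level
#' vectors must match too (the h5ad round trip preserves them; loom and text
#' round trips only preserve the observed values).
#'
#' @param a,b `cell_dataset` objects.
#' @param tol Absolute tolerance for the normalized layer.
#' @param strict_levels Compare factor level vectors exactly.
#' @return Character vector of differences; empty when equal.
#' @export
dataset_differences <- function(a, b, tol = 1e-12, strict_levels = FALSE) {
  d <- character()
  add <- function(fmt, ...) d <<- c(d, sprintf(fmt, ...))
  if (xor(is.null(a$counts), is.null(b$counts))) {
    add("counts: present in one dataset only")
  } else if (!is.null(a$counts)) {
    if (!identical(dim(a$counts), dim(b$counts))) {
      add("counts: shapes differ")
    } else if (!isTRUE(all(a$counts == b$counts))) {
      add("counts: values differ")
    }
  }
  if (!identical(dim(a$normalized), dim(b$normalized))) {
    add("normalized: shapes differ")
  } else {
    delta <- max(abs(a$normalized - b$normalized))
    if (!is.finite(delta) || delta > tol) {
      add("normalized: max abs difference %g exceeds %g", delta, tol)
    }
  }
  cmp_table <- function(x, y, what) {
    if (!identical(sort(names(x)), sort(names(y)))) {
      add("%s: column sets differ (%s vs %s)", what,
          paste(names(x), collapse = ","), paste(names(y), collapse = ","))
      return(invisible())
    }
    for (col in names(x)) {
      xv <- x[[col]]; yv <- y[[col]]
      if (is.factor(xv) && is.factor(yv)) {
        if (!identical(as.character(xv), as.character(yv))) {
          add("%s: column %s values differ", what, col)
        } else if (strict_levels && !identical(levels(xv), levels(yv))) {
          add("%s: column %s factor levels differ", what, col)
        }
      } else if (is.numeric(xv) && is.numeric(yv)) {
        if (length(xv) != length(yv) ||
            !isTRUE(all.equal(as.numeric(xv), as.numeric(yv),
                              tolerance = tol, scale = 1))) {
          add("%s: column %s values differ", what, col)
        }
      } else if (!identical(as.character(xv), as.character(yv))) {
        add("%s: column %s values/types differ", what, col)
      }
    }
  }
  cmp_table(a$cell_table, b$cell_table, "cell_table")
  cmp_table(a$gene_table, b$gene_table, "gene_table")
  if (!identical(sort(names(a$embeddings)), sort(names(b$embeddings)))) {
    add("embeddings: name sets differ")
  } else {
    for (nm in names(a$embeddings)) {
      if (!isTRUE(all.equal(a$embeddings[[nm]], b$embeddings[[nm]],
                            tolerance = tol, scale = 1))) {
        add("embeddings: '%s' coordinates differ", nm)
      }
    }
  }
  if (nrow(a$markers) != nrow(b$markers)) {
    add("markers: row counts differ")
  } else if (nrow(a$markers)) {
    cmp_table(a$markers, b$markers, "markers")
  }
  for (f in c("title", "short", "long")) {
    if (!identical(a$about[[f]], b$about[[f]])) {
      add("about: %s differs", f)
    }
  }
  d
}

#' @rdname dataset_differences
#' @export
dataset_equal <- function(a, b, tol = 1e-12, strict_levels = FALSE) {
  length(dataset_differences(a, b, tol = tol,
                             strict_levels = strict_levels)) == 0L
}

#' Restrict a dataset to a subset of its cells
#'
#' Keeps factor levels and gene annotation untouched so that summaries on
#' the subset dataset agree with subset-restricted summaries on the full
#' dataset.
#'
#' @param ds A `cell_dataset`.
#' @param cells Integer vector of 1-based cell indices.
#' @return A `cell_dataset` with `length(cells)` cells.
#' @export
subset_cells <- function(ds, cells) {
  cells <- as.integer(cells)
  if (length(cells) && (min(cells) < 1L || max(cells) > n_cells(ds))) {
    cd_stop("celldeck_spec_error", "cell indices out of range 1..%d",
            n_cells(ds))
  }
  out <- ds
  if (!is.null(ds$counts)) out$counts <- ds$counts[cells, , drop = FALSE]
  out$normalized <- ds$normalized[cells, , drop = FALSE]
  out$cell_table <- ds$cell_table[cells, , drop = FALSE]
  rownames(out$cell_table) <- NULL
  out$embeddings <- lapply(ds$embeddings, function(e) e[cells, , drop = FALSE])
  out
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("<cell_dataset> %s\n", x$about$title))
  cat(sprintf("  %d cells x %d genes (counts: %s)\n", n_cells(x), n_genes(x),
              if (is.null(x$counts)) "absent" else "present"))
  cat(sprintf("  cell columns: %s\n",
              paste(names(x$cell_table), collapse = ", ")))
  if (length(x$embeddings)) {
    cat(sprintf("  embeddings: %s\n",
                paste(names(x$embeddings), collapse = ", ")))
  }
  if (nrow(x$markers)) cat(sprintf("  markers: %d rows\n", nrow(x$markers)))
  invisible(x)
}
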