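# AnnData-layout HDF5 (h5ad) persistence.
#
# Layout written (and accepted on read):
#   X                normalized layer, CSR sparse (CSC also read)
#   layers/counts    raw UMI counts, CSR sparse
#   obs, var         dataframe groups; categorical columns as codes+categories
#   obsm/X_<name>    cells x 2 embeddings
#   uns/markers      marker table as a dataframe group
#   uns/about/{title,short,long}  scalar UTF-8 strings
#
# Element-level "encoding-type"/"encoding-version" attributes follow the
# AnnData on-disk spec (v0.8+ dialect) so files interoperate with
# scanpy/anndata. HDF5 stores arrays row-major while R is column-major, so
# 2-D datasets are transposed at the boundary: an R matrix written with dim
# (a, b) appears to C-order readers with shape (b, a).

ENC_VER <- c(anndata = "0.1.0", csr_matrix = "0.1.0", csc_matrix = "0.1.0",
             dataframe = "0.2.0", categorical = "0.2.0", array = "0.2.0",
             `string-array` = "0.2.0", string = "0.2.0", dict = "0.1.0")

h5_attr <- function(obj, name, value, scalar = FALSE) {
  if (is.logical(value)) value <- as.integer(value)  # no HDF5 bool in rhdf5
  rhdf5::h5writeAttribute(value, obj, name, asScalar = scalar,
                          variableLengthString = is.character(value),
                          encoding = "UTF-8")
}

h5_encoding <- function(fid, name, type) {
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj))
  h5_attr(obj, "encoding-type", type, scalar = TRUE)
  h5_attr(obj, "encoding-version", unname(ENC_VER[type]), scalar = TRUE)
  invisible()
}

h5_write_strings <- function(x, fid, name) {
  rhdf5::h5write(enc2utf8(as.character(x)), fid, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_encoding(fid, name, "string-array")
}

h5_write_scalar_string <- function(x, fid, name) {
  rhdf5::h5write(enc2utf8(as.character(x)), fid, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_encoding(fid, name, "string")
}

h5_write_numeric <- function(x, fid, name) {
  rhdf5::h5write(x, fid, name)
  h5_encoding(fid, name, "array")
}

h5_write_categorical <- function(x, fid, name) {
  rhdf5::h5createGroup(fid, name)
  rhdf5::h5write(as.integer(x) - 1L, fid, paste0(name, "/codes"))
  rhdf5::h5write(enc2utf8(levels(x)), fid, paste0(name, "/categories"),
                 variableLengthString = TRUE, encoding = "UTF-8")
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj))
  h5_attr(obj, "encoding-type", "categorical", scalar = TRUE)
  h5_attr(obj, "encoding-version", unname(ENC_VER[["categorical"]]),
          scalar = TRUE)
  h5_attr(obj, "ordered", FALSE, scalar = TRUE)
  invisible()
}

# sparse cells x genes matrix -> CSR group (data/indices/indptr + shape attr)
h5_write_csr <- function(m, fid, name) {
  m <- methods::as(methods::as(m, "generalMatrix"), "RsparseMatrix")
  rhdf5::h5createGroup(fid, name)
  rhdf5::h5write(m@x, fid, paste0(name, "/data"))
  rhdf5::h5write(m@j, fid, paste0(name, "/indices"))
  rhdf5::h5write(m@p, fid, paste0(name, "/indptr"))
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj))
  h5_attr(obj, "encoding-type", "csr_matrix", scalar = TRUE)
  h5_attr(obj, "encoding-version", unname(ENC_VER[["csr_matrix"]]),
          scalar = TRUE)
  h5_attr(obj, "shape", dim(m))
  invisible()
}

h5_write_dataframe <- function(df, fid, name, index, index_name = "_index") {
  rhdf5::h5createGroup(fid, name)
  h5_write_strings(index, fid, paste0(name, "/", index_name))
  for (col in names(df)) {
    path <- paste0(name, "/", col)
    v <- df[[col]]
    if (is.factor(v)) {
      h5_write_categorical(v, fid, path)
    } else if (is.numeric(v)) {
      h5_write_numeric(v, fid, path)
    } else {
      h5_write_strings(as.character(v), fid, path)
    }
  }
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj))
  h5_attr(obj, "encoding-type", "dataframe", scalar = TRUE)
  h5_attr(obj, "encoding-version", unname(ENC_VER[["dataframe"]]),
          scalar = TRUE)
  h5_attr(obj, "_index", index_name, scalar = TRUE)
  if (ncol(df)) {  # rhdf5 cannot write zero-length string attributes
    h5_attr(obj, "column-order", names(df))
  }
  invisible()
}

#' Save a dataset as an AnnData-layout HDF5 file
#'
#' Writes the normalized layer to `X` (CSR sparse), raw counts to
#' `layers/counts`, the annotation tables to `obs`/`var`, embeddings to
#' `obsm/X_<name>`, the marker table to `uns/markers` and the descriptive
#' metadata to `uns/about`. The file round-trips through
#' [load_dataset_file()]: counts bit-exact, normalized values within 1e-12,
#' tables, embeddings, markers and about equal.
#'
#' @param ds A valid `cell_dataset` ([validate_dataset()] must be clean).
#' @param destination Output file path (conventionally `.h5ad`).
#' @return Invisibly, `destination`.
#' @export
save_dataset <- function(ds, destination) {
  assert_valid_dataset(ds)
  if (n_cells(ds) == 0L || n_genes(ds) == 0L) {
    cd_stop("celldeck_spec_error", "refusing to save an empty dataset")
  }
  if (!dir.exists(dirname(destination))) {
    cd_stop("celldeck_io_error", "destination directory does not exist: %s",
            dirname(destination))
  }
  if (file.exists(destination)) unlink(destination)
  fid <- rhdf5::H5Fcreate(destination)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)

  h5_attr(fid, "encoding-type", "anndata", scalar = TRUE)
  h5_attr(fid, "encoding-version", unname(ENC_VER[["anndata"]]), scalar = TRUE)

  h5_write_csr(ds$normalized, fid, "X")
  rhdf5::h5createGroup(fid, "layers")
  if (!is.null(ds$counts)) h5_write_csr(ds$counts, fid, "layers/counts")

  obs_cols <- ds$cell_table[setdiff(names(ds$cell_table), "cell_id")]
  h5_write_dataframe(obs_cols, fid, "obs", index = ds$cell_table$cell_id)
  var_cols <- ds$gene_table[setdiff(names(ds$gene_table), "symbol")]
  h5_write_dataframe(var_cols, fid, "var", index = ds$gene_table$symbol)

  rhdf5::h5createGroup(fid, "obsm")
  for (nm in names(ds$embeddings)) {
    # transpose: R (2, n) on disk reads as (n, 2) for C-order consumers
    rhdf5::h5write(t(ds$embeddings[[nm]]), fid, paste0("obsm/X_", nm))
    h5_encoding(fid, paste0("obsm/X_", nm), "array")
  }

  rhdf5::h5createGroup(fid, "uns")
  h5_encoding(fid, "uns", "dict")
  rhdf5::h5createGroup(fid, "uns/about")
  h5_encoding(fid, "uns/about", "dict")
  for (f in c("title", "short", "long")) {
    h5_write_scalar_string(ds$about[[f]], fid, paste0("uns/about/", f))
  }
  if (nrow(ds$markers)) {
    h5_write_dataframe(ds$markers, fid, "uns/markers",
                       index = as.character(seq_len(nrow(ds$markers)) - 1L))
  }
  if (!is.null(ds$cluster_column)) {
    h5_write_scalar_string(ds$cluster_column, fid, "uns/cluster_column")
  }
  invisible(destination)
}

h5_read_sparse <- function(file, name, attrs) {
  shape <- as.integer(attrs$shape)
  data <- as.numeric(rhdf5::h5read(file, paste0(name, "/data")))
  indices <- as.integer(rhdf5::h5read(file, paste0(name, "/indices")))
  indptr <- as.integer(rhdf5::h5read(file, paste0(name, "/indptr")))
  enc <- as.character(attrs[["encoding-type"]])
  m <- if (length(enc) && enc == "csc_matrix") {
    Matrix::sparseMatrix(i = indices, p = indptr, x = data, dims = shape,
                         index1 = FALSE)
  } else {
    Matrix::sparseMatrix(j = indices, p = indptr, x = data, dims = shape,
                         index1 = FALSE)
  }
  as_dgc(m)
}

# matrix element: sparse group or dense dataset, -> cells x genes dgCMatrix
h5_read_matrix <- function(file, name, ls_tab) {
  row <- ls_tab[ls_tab$full == name, , drop = FALSE]
  if (row$otype == "H5I_GROUP") {
    attrs <- rhdf5::h5readAttributes(file, name)
    if (is.null(attrs$shape)) {
      cd_stop("celldeck_format_error",
              "%s: sparse group lacks a shape attribute", name)
    }
    h5_read_sparse(file, name, attrs)
  } else {
    # dense dataset: stored C-order (n_obs, n_vars) -> R reads transposed
    m <- rhdf5::h5read(file, name)
    as_dgc(t(m))
  }
}

h5_read_dataframe <- function(file, name, ls_tab) {
  attrs <- rhdf5::h5readAttributes(file, name)
  index_name <- if (!is.null(attrs$`_index`)) {
    as.character(attrs$`_index`)
  } else "_index"
  children <- ls_tab[ls_tab$group == name, , drop = FALSE]
  cols <- if (!is.null(attrs$`column-order`)) {
    as.character(attrs$`column-order`)
  } else setdiff(children$name, index_name)
  cols <- intersect(cols, children$name)
  index <- as.character(rhdf5::h5read(file, paste0(name, "/", index_name)))
  out <- list()
  for (col in cols) {
    path <- paste0(name, "/", col)
    child <- children[children$name == col, , drop = FALSE]
    if (child$otype == "H5I_GROUP") {
      sub <- ls_tab[ls_tab$group == path, "name"]
      if (all(c("codes", "categories") %in% sub)) {
        codes <- as.integer(rhdf5::h5read(file, paste0(path, "/codes")))
        cats <- as.character(rhdf5::h5read(file, paste0(path, "/categories")))
        v <- factor(ifelse(codes >= 0L, cats[codes + 1L], NA_character_),
                    levels = cats)
      } else if ("values" %in% sub) {  # nullable int/bool encodings
        v <- as.vector(rhdf5::h5read(file, paste0(path, "/values")))
      } else {
        cd_stop("celldeck_format_error",
                "%s: unsupported column encoding", path)
      }
    } else {
      v <- as.vector(rhdf5::h5read(file, path))
      if (is.raw(v)) v <- as.logical(v)
    }
    out[[col]] <- v
  }
  list(index = index, columns = as.data.frame(out, optional = TRUE,
                                              stringsAsFactors = FALSE))
}

#' Load a dataset from an AnnData-layout HDF5 file
#'
#' Accepts files written by [save_dataset()] as well as h5ad files written
#' by the scanpy/anndata ecosystem (v0.8+ on-disk dialect; CSR and CSC
#' sparse encodings, dense `X`). Missing optional components become empty
#' defaults; a missing `uns/about` block falls back to the file stem as the
#' title. When `X` holds whole numbers and no `layers/counts` exists, `X`
#' is interpreted as raw counts and the normalized layer is derived from it.
#'
#' @param source Path to an existing h5ad file.
#' @return A validated `cell_dataset`. Degenerate inputs (e.g. no stored
#'   embedding) load with a warning.
#' @export
load_dataset_file <- function(source) {
  if (!file.exists(source)) {
    cd_stop("celldeck_io_error", "no such file: %s", source)
  }
  if (!isTRUE(rhdf5::H5Fis_hdf5(source))) {
    cd_stop("celldeck_format_error", "not an HDF5 file: %s", source)
  }
  ls_tab <- rhdf5::h5ls(source)
  ls_tab$full <- ifelse(ls_tab$group == "/", paste0("/", ls_tab$name),
                        paste(ls_tab$group, ls_tab$name, sep = "/"))
  has <- function(p) p %in% ls_tab$full

  if (!has("/X")) {
    cd_stop("celldeck_format_error", "malformed h5ad: missing X matrix")
  }
  X <- h5_read_matrix(source, "/X", ls_tab)
  counts <- if (has("/layers/counts")) {
    h5_read_matrix(source, "/layers/counts", ls_tab)
  }

  if (!has("/obs") || !has("/var")) {
    cd_stop("celldeck_format_error", "malformed h5ad: missing obs/var table")
  }
  obs <- h5_read_dataframe(source, "/obs", ls_tab)
  var <- h5_read_dataframe(source, "/var", ls_tab)

  bind_cols <- function(base, extra) {
    if (!ncol(extra)) return(base)
    cbind(base, extra)
  }
  cell_table <- bind_cols(data.frame(cell_id = obs$index,
                                     stringsAsFactors = FALSE),
                          obs$columns)
  symbol <- var$index
  gene_cols <- var$columns
  gene_id <- if ("gene_id" %in% names(gene_cols)) {
    as.character(gene_cols$gene_id)
  } else symbol
  gene_table <- bind_cols(data.frame(gene_id = gene_id, symbol = symbol,
                                     stringsAsFactors = FALSE),
                          gene_cols[setdiff(names(gene_cols), "gene_id")])

  embeddings <- list()
  obsm_keys <- ls_tab[ls_tab$group == "/obsm", "name"]
  for (key in obsm_keys) {
    nm <- sub("^X_", "", key)
    coords <- t(rhdf5::h5read(source, paste0("/obsm/", key)))
    if (ncol(coords) >= 2L) {
      embeddings[[nm]] <- coords[, 1:2, drop = FALSE]
    }
  }
  if (!length(embeddings)) {
    cd_warn("%s: no 2-D embedding stored; scatter views will be unavailable",
            basename(source))
  }

  markers <- NULL
  if (has("/uns/markers")) {
    markers <- h5_read_dataframe(source, "/uns/markers", ls_tab)$columns
  }

  stem <- sub("\\.h5ad$", "", basename(source))
  about <- list(title = stem, short = "", long = "")
  if (has("/uns/about")) {
    for (f in c("title", "short", "long")) {
      p <- paste0("/uns/about/", f)
      if (has(p)) about[[f]] <- as.character(rhdf5::h5read(source, p))
    }
  }
  cluster_column <- if (has("/uns/cluster_column")) {
    as.character(rhdf5::h5read(source, "/uns/cluster_column"))
  }

  if (is.null(counts) && is_count_matrix(X)) {
    counts <- X
    X <- NULL
  }
  ds <- cell_dataset(counts = counts, normalized = X,
                     cell_table = cell_table, gene_table = gene_table,
                     embeddings = embeddings, markers = markers,
                     about = about, cluster_column = cluster_column)
  assert_valid_dataset(ds)
  ds
}
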