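# Plot-ready summary statistics: dot plots, composition tables, species-mix
# statistics, distribution panels, scatter downsampling. Every operation
# accepts an optional cell subset and is consistent with physically
# subsetting the dataset first.

resolve_cells <- function(ds, cells) {
  if (is.null(cells)) return(seq_len(n_cells(ds)))
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) && (min(cells) < 1L || max(cells) > n_cells(ds))) {
    cd_stop("celldeck_spec_error", "cell indices out of range 1..%d",
            n_cells(ds))
  }
  cells
}

require_categorical <- function(ds, column) {
  if (!column %in% names(ds$cell_table)) {
    cd_stop("celldeck_spec_error", "unknown cell column: %s", column)
  }
  v <- ds$cell_table[[column]]
  if (!is.factor(v)) {
    cd_stop("celldeck_spec_error", "column %s is not categorical", column)
  }
  v
}

resolve_genes <- function(ds, genes) {
  idx <- match(genes, ds$gene_table$symbol)
  if (anyNA(idx)) {
    cd_stop("celldeck_spec_error", "unknown gene symbol(s): %s",
            paste(genes[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Dot-plot summary statistics
#'
#' For each gene and each observed group (optionally subdivided by a split
#' column, the "split dot plot" of stimulated-vs-control comparisons),
#' computes the mean normalized expression over all cells of the group
#' (zeros included) and the fraction of those cells expressing the gene
#' (stored value > 0). Group/split combinations with no cells are omitted,
#' not zero-filled.
#'
#' @param ds A `cell_dataset`.
#' @param genes Character vector of gene symbols (unknown symbols error,
#'   listing the offenders).
#' @param group_by Categorical cell column defining the dot rows.
#' @param split_by Optional second categorical column subdividing each
#'   group.
#' @param cells Optional cell subset (1-based indices; default all).
#' @return A `dot_plot_summary` data frame with columns `gene`, `group`,
#'   (`split`,) `mean`, `fraction`, ordered by gene, then group level, then
#'   split level.
#' @export
dot_plot_summary <- function(ds, genes, group_by, split_by = NULL,
                             cells = NULL) {
  gidx <- resolve_genes(ds, genes)
  grp <- require_categorical(ds, group_by)
  spl <- if (!is.null(split_by)) require_categorical(ds, split_by)
  cells <- resolve_cells(ds, cells)
  grp <- grp[cells]
  if (!is.null(spl)) spl <- spl[cells]
  key <- if (is.null(spl)) {
    factor(grp, levels = levels(grp))
  } else {
    interaction(grp, spl, sep = "\r", lex.order = TRUE)
  }
  occupied <- levels(key)[tabulate(key, nbins = nlevels(key)) > 0L]
  rows <- list()
  for (j in seq_along(genes)) {
    v <- as.numeric(ds$normalized[cells, gidx[j]])
    means <- tapply(v, key, mean)
    fracs <- tapply(v > 0, key, mean)
    for (lev in occupied) {
      parts <- strsplit(lev, "\r", fixed = TRUE)[[1]]
      row <- list(gene = genes[j], group = parts[1])
      if (!is.null(spl)) row$split <- parts[2]
      row$mean <- unname(means[[lev]])
      row$fraction <- unname(fracs[[lev]])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dot_plot_summary", "data.frame")
  out
}

#' Cross-tabulated composition of one categorical by another
#'
#' Counts and within-primary proportions of each secondary level per
#' primary level (e.g. species composition of each cluster). Declared
#' levels with zero cells are retained with count 0; proportions of an
#' empty primary level are reported as 0 with `defined = FALSE`.
#'
#' @param ds A `cell_dataset`.
#' @param primary,secondary Categorical cell columns.
#' @param cells Optional cell subset (default all).
#' @return A `composition_table` data frame with columns `primary`,
#'   `secondary`, `n`, `proportion`, `defined`.
#' @export
composition_table <- function(ds, primary, secondary, cells = NULL) {
  pv <- require_categorical(ds, primary)
  sv <- require_categorical(ds, secondary)
  cells <- resolve_cells(ds, cells)
  tab <- table(primary = pv[cells], secondary = sv[cells])
  totals <- rowSums(tab)
  rows <- expand.grid(secondary = colnames(tab), primary = rownames(tab),
                      stringsAsFactors = FALSE)[, c("primary", "secondary")]
  n <- mapply(function(p, s) tab[p, s], rows$primary, rows$secondary)
  tot <- totals[rows$primary]
  out <- data.frame(primary = rows$primary, secondary = rows$secondary,
                    n = as.integer(n),
                    proportion = ifelse(tot > 0, n / pmax(tot, 1), 0),
                    defined = tot > 0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Species-mixing statistics and doublet calling
#'
#' For a two-species (barnyard) experiment: calls each cell species 1 when
#' the species-1 UMI fraction reaches `purity_threshold`, species 2 when
#' the species-2 fraction does, and doublet otherwise, then reports the
#' aggregate doublet rate and per-call cell counts.
#'
#' @param h_counts,m_counts Per-cell UMI counts for species 1 and 2
#'   (equal length, non-negative; each cell must have at least one UMI).
#' @param purity_threshold Minimum UMI fraction for a singlet call
#'   (default 0.9).
#' @return A `species_mix_stats` list: `per_cell` data frame (`h`, `m`,
#'   `call`), `doublet_rate`, `n_species1`, `n_species2`, `n_doublet`.
#' @export
species_mix_stats <- function(h_counts, m_counts, purity_threshold = 0.9) {
  h <- as.numeric(h_counts); m <- as.numeric(m_counts)
  if (length(h) != length(m)) {
    cd_stop("celldeck_spec_error", "count vectors differ in length")
  }
  if (any(h < 0) || any(m < 0)) {
    cd_stop("celldeck_spec_error", "counts must be non-negative")
  }
  zero <- which(h + m == 0)
  if (length(zero)) {
    cd_stop("celldeck_domain_error",
            "cell(s) with zero total UMIs: %s",
            paste(utils::head(zero, 5L), collapse = ", "))
  }
  frac_h <- h / (h + m)
  call <- ifelse(frac_h >= purity_threshold, "species1",
                 ifelse(1 - frac_h >= purity_threshold, "species2",
                        "doublet"))
  call <- factor(call, levels = c("species1", "species2", "doublet"))
  structure(list(
    per_cell = data.frame(h = h, m = m, call = call),
    doublet_rate = mean(call == "doublet"),
    n_species1 = sum(call == "species1"),
    n_species2 = sum(call == "species2"),
    n_doublet = sum(call == "doublet")
  ), class = "species_mix_stats")
}

#' @export
print.species_mix_stats <- function(x, ...) {
  cat(sprintf("species mix: %d cells (%d / %d singlets, %d doublets), doublet rate %.4f\n",
              nrow(x$per_cell), x$n_species1, x$n_species2, x$n_doublet,
              x$doublet_rate))
  invisible(x)
}

#' Per-group value distributions for violin/box panels
#'
#' Resolves `value` as a gene symbol (normalized layer) or a numeric cell
#' column; a name matching both is an ambiguity error and must be qualified
#' as `gene:<name>` or `column:<name>`. Quartiles use linear interpolation
#' (type 7), the R default, fixed for cross-implementation reproducibility.
#'
#' @param ds A `cell_dataset`.
#' @param value Gene symbol or numeric column name (optionally qualified).
#' @param group_by Categorical cell column.
#' @param cells Optional cell subset (default all).
#' @return A `distribution_panel` list: `values` (named list of per-group
#'   numeric vectors, declared level order, empty groups dropped) and
#'   `summary` (data frame `group`, `n`, `median`, `q1`, `q3`).
#' @export
distribution_panel <- function(ds, value, group_by, cells = NULL) {
  grp <- require_categorical(ds, group_by)
  cells <- resolve_cells(ds, cells)
  qualified <- regmatches(value, regexec("^(gene|column):(.*)$", value))[[1]]
  kind <- if (length(qualified)) qualified[2] else NA_character_
  name <- if (length(qualified)) qualified[3] else value
  as_gene <- name %in% ds$gene_table$symbol
  as_col <- name %in% names(ds$cell_table) &&
    is.numeric(ds$cell_table[[name]])
  if (is.na(kind)) {
    if (as_gene && as_col) {
      cd_stop("celldeck_spec_error",
              "'%s' is both a gene and a column; qualify as gene:%s or column:%s",
              name, name, name)
    }
    kind <- if (as_gene) "gene" else if (as_col) "column" else {
      cd_stop("celldeck_spec_error",
              "'%s' is neither a gene symbol nor a numeric column", name)
    }
  }
  v <- if (kind == "gene") {
    as.numeric(ds$normalized[cells, resolve_genes(ds, name)])
  } else {
    if (!as_col) {
      cd_stop("celldeck_spec_error", "unknown numeric column: %s", name)
    }
    as.numeric(ds$cell_table[[name]][cells])
  }
  g <- grp[cells]
  values <- list()
  rows <- list()
  for (lev in levels(g)) {
    vals <- v[g == lev]
    if (!length(vals)) next
    values[[lev]] <- vals
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      group = lev, n = length(vals), median = q[2], q1 = q[1], q3 = q[3],
      stringsAsFactors = FALSE)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(), n = integer(), median = numeric(),
               q1 = numeric(), q3 = numeric(), stringsAsFactors = FALSE)
  }
  rownames(summary) <- NULL
  structure(list(values = values, summary = summary),
            class = "distribution_panel")
}

#' Reproducible scatter-plot downsampling
#'
#' Identity when the dataset fits; otherwise a uniform sample without
#' replacement, reproducible given the seed and independent of the caller's
#' RNG state.
#'
#' @param n_cells_total Number of cells available.
#' @param max_points Maximum points to retain (>= 1).
#' @param seed Integer seed.
#' @return Sorted integer vector of retained 1-based indices.
#' @export
downsample_cells <- function(n_cells_total, max_points, seed = 1L) {
  if (max_points < 1L) {
    cd_stop("celldeck_spec_error", "max_points must be >= 1")
  }
  if (n_cells_total <= max_points) {
    return(seq_len(n_cells_total))
  }
  with_seed(seed, sort(sample.int(n_cells_total, max_points)))
}
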