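# On-the-fly two-group differential expression: Wilcoxon rank-sum per gene
# on the normalized layer, Benjamini-Hochberg correction over tested genes.

#' Differential expression parameters
#'
#' @param min_cells_per_group Minimum cells per group (>= 2; default 3).
#' @param min_fraction_expressed Gene is tested when at least this fraction
#'   of cells expresses it (stored value > 0) in either group; default 0.1.
#' @param top_n Optional row cap applied after sorting.
#' @param epsilon Regularizer added to both de-logged group means before the
#'   fold-change ratio, avoiding division by zero (default 1e-9).
#' @return A `diffexp_params` object.
#' @export
diffexp_params <- function(min_cells_per_group = 3L,
                           min_fraction_expressed = 0.1, top_n = NULL,
                           epsilon = 1e-9) {
  if (min_cells_per_group < 2L) {
    cd_stop("celldeck_spec_error", "min_cells_per_group must be >= 2")
  }
  if (min_fraction_expressed < 0 || min_fraction_expressed > 1) {
    cd_stop("celldeck_spec_error",
            "min_fraction_expressed must be in [0, 1]")
  }
  structure(list(min_cells_per_group = as.integer(min_cells_per_group),
                 min_fraction_expressed = min_fraction_expressed,
                 top_n = top_n, epsilon = epsilon),
            class = "diffexp_params")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null distribution when the pooled sample size is at most 12 and no
#' ties are present; otherwise the normal approximation with tie-corrected
#' variance and no continuity correction. The statistic is the Mann-Whitney
#' U of `x`. The p-value is clamped to (0, 1]; a degenerate comparison with
#' zero rank variance (all values tied) yields p = 1.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return `list(statistic, p_value)`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    cd_stop("celldeck_spec_error",
            "rank_sum_test needs >= 2 values per group (got %d and %d)",
            length(x), length(y))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  p <- res$p.value
  if (!is.finite(p)) p <- 1  # zero tie-corrected variance
  list(statistic = unname(res$statistic), p_value = min(max(p, 1e-300), 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: order p-values ascending, multiply the i-th by m/i, enforce
#' monotonicity by a running minimum from the largest rank, cap at 1 and
#' return in the original order.
#'
#' @param p_values Numeric vector with all values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) && (anyNA(p) || any(p < 0) || any(p > 1))) {
    cd_stop("celldeck_spec_error", "p-values must all lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential gene expression
#'
#' Compares two manually defined, disjoint cell groups on the normalized
#' layer. Genes expressed (stored value > 0) in less than
#' `min_fraction_expressed` of the cells of both groups are excluded before
#' testing, and the BH correction uses only the tested genes. The log2 fold
#' change is `log2((mu_A + eps) / (mu_B + eps))` on the de-logged
#' (`expm1`) group means of the normalized layer. Rows are sorted by
#' ascending p-value, ties broken by descending absolute fold change, then
#' by symbol, so results are reproducible.
#'
#' @param ds A `cell_dataset`.
#' @param groups A `group_assignment` (or named list) with exactly two
#'   groups; the first is the "A" side of the fold change.
#' @param params A [diffexp_params()] object.
#' @return A `diffexp_result`: data frame with columns `symbol`,
#'   `statistic`, `p`, `p_adj`, `log2fc`, `mean_a`, `mean_b`, `frac_a`,
#'   `frac_b`; attributes `n_untested`, `group_labels`, `group_sizes`.
#' @export
differential_expression <- function(ds, groups, params = diffexp_params()) {
  if (length(groups) != 2L) {
    cd_stop("celldeck_spec_error",
            "differential expression needs exactly 2 groups (got %d)",
            length(groups))
  }
  labels <- names(groups)
  a <- as.integer(groups[[1]]); b <- as.integer(groups[[2]])
  if (length(intersect(a, b))) {
    cd_stop("celldeck_spec_error", "groups %s and %s overlap",
            labels[1], labels[2])
  }
  for (i in 1:2) {
    sz <- length(groups[[i]])
    if (sz < params$min_cells_per_group) {
      cd_stop("celldeck_spec_error",
              "group %s has %d cells (minimum %d)", labels[i], sz,
              params$min_cells_per_group)
    }
  }
  norm_a <- ds$normalized[a, , drop = FALSE]
  norm_b <- ds$normalized[b, , drop = FALSE]
  frac_a <- Matrix::colMeans(norm_a > 0)
  frac_b <- Matrix::colMeans(norm_b > 0)
  tested <- which(frac_a >= params$min_fraction_expressed |
                    frac_b >= params$min_fraction_expressed)
  n_untested <- n_genes(ds) - length(tested)

  mean_a <- Matrix::colMeans(norm_a)
  mean_b <- Matrix::colMeans(norm_b)
  mu_a <- Matrix::colMeans(expm1_sparse(norm_a))
  mu_b <- Matrix::colMeans(expm1_sparse(norm_b))
  eps <- params$epsilon
  log2fc <- log2((mu_a + eps) / (mu_b + eps))

  stat <- p <- numeric(length(tested))
  for (k in seq_along(tested)) {
    g <- tested[k]
    r <- rank_sum_test(as.numeric(norm_a[, g]), as.numeric(norm_b[, g]))
    stat[k] <- r$statistic
    p[k] <- r$p_value
  }
  p_adj <- benjamini_hochberg(p)
  sym <- ds$gene_table$symbol[tested]
  out <- data.frame(symbol = sym, statistic = stat, p = p, p_adj = p_adj,
                    log2fc = log2fc[tested], mean_a = mean_a[tested],
                    mean_b = mean_b[tested], frac_a = frac_a[tested],
                    frac_b = frac_b[tested], stringsAsFactors = FALSE)
  ord <- order(out$p, -abs(out$log2fc), out$symbol)
  out <- out[ord, , drop = FALSE]
  if (!is.null(params$top_n)) {
    out <- utils::head(out, params$top_n)
  }
  rownames(out) <- NULL
  structure(out, class = c("diffexp_result", "data.frame"),
            n_untested = n_untested, group_labels = labels,
            group_sizes = c(length(a), length(b)))
}

# expm1 on the non-zero entries of a sparse matrix
expm1_sparse <- function(m) {
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m@x <- expm1(m@x)
  m
}

#' @export
print.diffexp_result <- function(x, ...) {
  labels <- attr(x, "group_labels")
  sizes <- attr(x, "group_sizes")
  cat(sprintf("differential expression %s (n=%d) vs %s (n=%d): %d genes tested, %d skipped\n",
              labels[1], sizes[1], labels[2], sizes[2], nrow(x),
              attr(x, "n_untested")))
  print.data.frame(utils::head(x, 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Serialize a differential expression result to TSV
#'
#' @param result A `diffexp_result`.
#' @return TSV text with the documented column order.
#' @export
diffexp_to_tsv <- function(result) {
  format_tsv(as.data.frame(result))
}
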