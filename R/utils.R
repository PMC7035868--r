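# internal helpers shared across modules

#' Evaluate code under a temporary, fixed RNG state
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their seed and never disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# stop with a classed condition so callers can distinguish error kinds
cd_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "celldeck_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

cd_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# coerce any numeric matrix (dense or sparse, integer or double) to dgCMatrix
as_dgc <- function(m) {
  if (is.matrix(m)) {
    storage.mode(m) <- "double"
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# TRUE when all stored values are whole numbers (works for sparse matrices)
is_count_matrix <- function(m) {
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  length(x) == 0L || (all(is.finite(x)) && all(x >= 0) && all(x == floor(x)))
}

#' Serialize a data frame to TSV text
#'
#' The single serializer used for every downloadable table (differential
#' expression results, dot-plot and composition summaries) so that payloads
#' produced by the web service are byte-identical to direct library calls.
#'
#' @param df A data frame.
#' @return A single string: tab-separated values with a header line and
#'   trailing newline; no quoting, no row names.
#' @export
format_tsv <- function(df) {
  con <- textConnection(NULL, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  paste0(paste(textConnectionValue(con), collapse = "\n"), "\n")
}
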