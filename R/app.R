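# Application layer: configuration, the command-line converter, and the
# JSON/TSV web service. The service layer adds no computation of its own:
# every numeric payload is produced by the selection / diffexp / summaries
# functions and serialized with the same helpers a direct library call
# would use.

#' Application configuration
#'
#' Data sources may come from the `data_sources` argument (repeatable CLI
#' flag) or, when that is empty, from the `CELLDECK_DATA_SOURCES`
#' environment variable (semicolon-separated URLs); explicit arguments win.
#'
#' @param data_sources Character vector of dataset or folder URLs/paths.
#' @param cache_dir Download cache directory.
#' @param host,port Bind address for [run_server()].
#' @param max_scatter_points Scatter downsampling cap (default 50,000).
#' @param upload_enabled Accept dataset uploads over HTTP.
#' @param conversion_enabled Expose the converter in the service.
#' @return An `app_config` object.
#' @export
app_config <- function(data_sources = character(),
                       cache_dir = file.path(tempdir(), "celldeck-cache"),
                       host = "127.0.0.1", port = 8050L,
                       max_scatter_points = 50000L,
                       upload_enabled = FALSE, conversion_enabled = TRUE) {
  if (!length(data_sources)) {
    env <- Sys.getenv("CELLDECK_DATA_SOURCES", "")
    if (nzchar(env)) {
      data_sources <- trimws(strsplit(env, ";", fixed = TRUE)[[1]])
      data_sources <- data_sources[nzchar(data_sources)]
    }
  }
  if (!length(data_sources) && !upload_enabled) {
    cd_stop("celldeck_spec_error",
            "need at least one data source or upload_enabled = TRUE")
  }
  port <- as.integer(port)
  if (is.na(port) || port < 1L || port > 65535L) {
    cd_stop("celldeck_spec_error", "port must be in 1..65535")
  }
  structure(list(data_sources = data_sources, cache_dir = cache_dir,
                 host = host, port = port,
                 max_scatter_points = as.integer(max_scatter_points),
                 upload_enabled = isTRUE(upload_enabled),
                 conversion_enabled = isTRUE(conversion_enabled)),
            class = "app_config")
}

#' Command-line converter
#'
#' Auto-detects the input format (a directory containing `matrix.mtx` is
#' CellRanger output, a `.loom` file is loom, a `.h5ad` file is passed
#' through, and a pair of files is a text matrix + annotation) unless
#' `format` forces one, converts, saves the h5ad container and prints the
#' report.
#'
#' @param inputs Character vector of input paths (1 for cellranger / loom /
#'   h5ad, 2 for text).
#' @param output Output `.h5ad` path.
#' @param format `NULL` (auto) or one of `"cellranger"`, `"loom"`,
#'   `"text"`, `"h5ad"`.
#' @param about_file Optional JSON or YAML-less `key: value` text file with
#'   `title`, `short`, `long`.
#' @return The `conversion_report`, invisibly.
#' @export
cli_convert <- function(inputs, output, format = NULL, about_file = NULL) {
  about <- if (!is.null(about_file)) read_about_file(about_file)
  if (is.null(format)) {
    format <- detect_input_format(inputs)
  }
  res <- switch(format,
    cellranger = convert_cellranger(inputs[1], about = about),
    loom = convert_loom(inputs[1], about = about),
    text = {
      if (length(inputs) != 2L) {
        cd_stop("celldeck_spec_error",
                "text conversion needs MATRIX and ANNOTATION inputs")
      }
      convert_text(inputs[1], inputs[2], about = about)
    },
    h5ad = {
      ds <- load_dataset_file(inputs[1])
      if (!is.null(about)) ds$about <- dataset_about(about, ds$about$title)
      list(dataset = ds,
           report = conversion_report(n_cells(ds), n_genes(ds), character(),
                                      "h5ad"))
    },
    cd_stop("celldeck_spec_error", "unknown format: %s", format))
  save_dataset(res$dataset, output)
  print(res$report)
  invisible(res$report)
}

detect_input_format <- function(inputs) {
  if (length(inputs) == 2L) return("text")
  if (length(inputs) != 1L) {
    cd_stop("celldeck_spec_error",
            "expected 1 input (or 2 for text); use --format to disambiguate")
  }
  p <- inputs[1]
  if (dir.exists(p)) {
    if (!is.na(find_input_file(p, "matrix.mtx"))) return("cellranger")
    cd_stop("celldeck_spec_error",
            "directory %s has no matrix.mtx; use --format", p)
  }
  if (grepl("\\.loom$", p)) return("loom")
  if (grepl("\\.h5ad$", p)) return("h5ad")
  cd_stop("celldeck_spec_error",
          "cannot detect format of %s; use --format", p)
}

read_about_file <- function(path) {
  if (!file.exists(path)) {
    cd_stop("celldeck_io_error", "no such about file: %s", path)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(txt), error = function(e) NULL)
  if (is.list(parsed)) return(parsed)
  # fall back to "key: value" lines
  lines <- strsplit(txt, "\n")[[1]]
  kv <- regmatches(lines, regexec("^(title|short|long)\\s*:\\s*(.*)$",
                                  lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2]]] <- m[3]
  out
}

# ------------------------------------------------------------------ service

# mutable service state: catalog entries plus lazily loaded datasets
new_app_state <- function(config) {
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$datasets <- new.env(parent = emptyenv())
  entries <- list()
  errors <- character()
  for (src in config$data_sources) {
    url <- tryCatch(parse_source_url(src), error = function(e) e)
    if (inherits(url, "error")) {
      errors <- c(errors, conditionMessage(url))
      next
    }
    if (url$scheme == "file" && dir.exists(url$path)) {
      cat_tab <- tryCatch(list_catalog(url), error = function(e) NULL)
      if (!is.null(cat_tab) && nrow(cat_tab)) {
        for (i in seq_len(nrow(cat_tab))) {
          entries[[cat_tab$id[i]]] <- list(
            id = cat_tab$id[i], source = cat_tab$source[i],
            title = cat_tab$title[i], short = cat_tab$short[i])
        }
      }
    } else {
      id <- sub("\\.h5ad$", "", basename(url$path))
      entries[[id]] <- list(id = id, source = src, title = id, short = "")
    }
  }
  state$entries <- entries[order(names(entries))]
  state$source_errors <- errors
  state
}

get_dataset <- function(state, id) {
  if (!id %in% names(state$entries)) {
    cd_stop("celldeck_spec_error", "unknown dataset: %s", id)
  }
  if (!exists(id, envir = state$datasets, inherits = FALSE)) {
    src <- state$entries[[id]]$source
    ds <- suppressWarnings(fetch_dataset(src,
                                         cache_dir = state$config$cache_dir))
    assign(id, ds, envir = state$datasets)
  }
  get(id, envir = state$datasets, inherits = FALSE)
}

json_response <- function(x, status = 200L) {
  list(status = status,
       headers = list("Content-Type" = "application/json"),
       body = as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

tsv_response <- function(text) {
  list(status = 200L,
       headers = list("Content-Type" = "text/tab-separated-values"),
       body = text)
}

error_response <- function(message, status = 400L) {
  json_response(list(error = message), status = status)
}

read_body <- function(req) {
  raw <- req$rook.input$read()
  if (!length(raw)) return(NULL)
  jsonlite::fromJSON(rawToChar(raw), simplifyVector = FALSE)
}

body_cells <- function(body) {
  if (is.null(body$cells)) NULL else unlist(body$cells, use.names = FALSE)
}

# route one request against the state; returns a response list
handle_request <- function(state, req) {
  path <- req$PATH_INFO
  method <- req$REQUEST_METHOD
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  tryCatch({
    if (identical(path, "/api/catalog") && method == "GET") {
      return(json_response(list(
        datasets = unname(lapply(state$entries, function(e) {
          e[c("id", "title", "short")]
        })),
        errors = state$source_errors)))
    }
    if (length(parts) >= 4L && parts[1] == "api" && parts[2] == "dataset") {
      id <- parts[3]
      verb <- parts[4]
      if (verb == "about" && method == "GET") {
        ds <- get_dataset(state, id)
        return(json_response(ds$about))
      }
      if (verb == "meta" && method == "GET") {
        ds <- get_dataset(state, id)
        cols <- lapply(names(ds$cell_table), function(nm) {
          v <- ds$cell_table[[nm]]
          list(name = nm,
               kind = if (is.factor(v)) "categorical" else "numeric",
               levels = if (is.factor(v)) I(levels(v)) else NULL)
        })
        return(json_response(list(
          n_cells = n_cells(ds), n_genes = n_genes(ds),
          columns = cols, embeddings = I(names(ds$embeddings)),
          genes = I(ds$gene_table$symbol),
          markers = nrow(ds$markers))))
      }
      if (verb == "markers" && method == "GET") {
        ds <- get_dataset(state, id)
        return(tsv_response(format_tsv(ds$markers)))
      }
      if (verb == "filter" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        spec <- filter_spec_from_json(
          as.character(jsonlite::toJSON(body$filters, auto_unbox = TRUE,
                                        digits = NA)))
        cells <- apply_filter(ds, spec)
        return(json_response(list(cells = I(cells), n = length(cells))))
      }
      if (verb == "diffexp" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        groups <- assign_groups(lapply(body$groups, function(g) {
          unlist(g, use.names = FALSE)
        }))
        params <- do.call(diffexp_params, body$params %||% list())
        res <- differential_expression(ds, groups, params)
        return(tsv_response(diffexp_to_tsv(res)))
      }
      if (verb == "dotplot" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        out <- dot_plot_summary(ds,
                                genes = unlist(body$genes, use.names = FALSE),
                                group_by = body$group_by,
                                split_by = body$split_by,
                                cells = body_cells(body))
        return(tsv_response(format_tsv(out)))
      }
      if (verb == "composition" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        out <- composition_table(ds, primary = body$primary,
                                 secondary = body$secondary,
                                 cells = body_cells(body))
        return(tsv_response(format_tsv(out)))
      }
      if (verb == "distribution" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        out <- distribution_panel(ds, value = body$value,
                                  group_by = body$group_by,
                                  cells = body_cells(body))
        return(json_response(list(values = out$values,
                                  summary = out$summary)))
      }
      if (verb == "scatter" && method == "POST") {
        ds <- get_dataset(state, id)
        body <- read_body(req)
        emb <- body$embedding %||% names(ds$embeddings)[1]
        if (is.null(emb) || !emb %in% names(ds$embeddings)) {
          return(error_response(sprintf("unknown embedding: %s", emb)))
        }
        keep <- body_cells(body) %||% seq_len(n_cells(ds))
        keep <- keep[downsample_cells(length(keep),
                                      state$config$max_scatter_points,
                                      seed = body$seed %||% 1L)]
        coords <- ds$embeddings[[emb]][keep, , drop = FALSE]
        return(json_response(list(cells = I(keep),
                                  x = I(coords[, 1]), y = I(coords[, 2]))))
      }
    }
    if (identical(path, "/api/upload") && method == "POST") {
      if (!state$config$upload_enabled) {
        return(error_response("uploads are disabled", status = 403L))
      }
      raw <- req$rook.input$read()
      dir.create(file.path(state$config$cache_dir, "uploads"),
                 recursive = TRUE, showWarnings = FALSE)
      id <- paste0("upload-", substr(digest::digest(raw), 1, 8))
      dest <- file.path(state$config$cache_dir, "uploads",
                        paste0(id, ".h5ad"))
      writeBin(raw, dest)
      ds <- tryCatch(suppressWarnings(load_dataset_file(dest)),
                     error = function(e) {
                       unlink(dest)
                       cd_stop("celldeck_format_error",
                               "uploaded file is not a valid dataset: %s",
                               conditionMessage(e))
                     })
      state$entries[[id]] <- list(id = id, source = dest,
                                  title = ds$about$title,
                                  short = ds$about$short)
      state$entries <- state$entries[order(names(state$entries))]
      assign(id, ds, envir = state$datasets)
      return(json_response(list(id = id, title = ds$about$title)))
    }
    error_response(sprintf("no route for %s %s", method, path),
                   status = 404L)
  }, celldeck_error = function(e) {
    error_response(conditionMessage(e))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the exploration web service
#'
#' Serves the dataset catalog and per-dataset views over HTTP. Routes
#' (1-based cell indices throughout, matching the library surface):
#' \describe{
#'   \item{GET /api/catalog}{dataset list and source errors}
#'   \item{GET /api/dataset/ID/about}{title / short / long markdown}
#'   \item{GET /api/dataset/ID/meta}{columns, embeddings, gene symbols}
#'   \item{GET /api/dataset/ID/markers}{marker table as TSV}
#'   \item{POST /api/dataset/ID/filter}{`{"filters": [...]}` (the
#'     [filter_spec_to_json()] form) -> matching cell indices}
#'   \item{POST /api/dataset/ID/diffexp}{`{"groups": {"A": [...], "B":
#'     [...]}, "params": {...}}` -> TSV result table}
#'   \item{POST /api/dataset/ID/dotplot}{`{"genes": [...], "group_by":
#'     ..., "split_by": ..., "cells": [...]}` -> TSV}
#'   \item{POST /api/dataset/ID/composition}{`{"primary": ...,
#'     "secondary": ..., "cells": [...]}` -> TSV}
#'   \item{POST /api/dataset/ID/distribution}{`{"value": ..., "group_by":
#'     ...}` -> JSON per-group values and quartile summary}
#'   \item{POST /api/dataset/ID/scatter}{embedding coordinates, uniformly
#'     downsampled to the configured point cap}
#'   \item{POST /api/upload}{raw h5ad bytes -> new catalog entry (when
#'     enabled)}
#' }
#' Datasets are loaded lazily on first access; a source that fails to parse
#' is reported in the catalog's `errors` field rather than aborting
#' startup.
#'
#' @param config An [app_config()].
#' @param blocking Serve forever (`TRUE`) or return the server handle
#'   (`FALSE`, for programmatic use; stop it with `httpuv::stopServer()`).
#' @return The `httpuv` server handle (invisibly when blocking).
#' @export
run_server <- function(config, blocking = interactive() == FALSE) {
  state <- new_app_state(config)
  app <- list(call = function(req) handle_request(state, req))
  server <- tryCatch(
    httpuv::startServer(config$host, config$port, app),
    error = function(e) {
      cd_stop("celldeck_io_error", "cannot bind %s:%d: %s", config$host,
              config$port, conditionMessage(e))
    })
  if (blocking) {
    on.exit(httpuv::stopServer(server))
    message(sprintf("celldeck serving %d dataset(s) on http://%s:%d",
                    length(state$entries), config$host, config$port))
    repeat httpuv::service(1000L)
  } else {
    server
  }
}
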