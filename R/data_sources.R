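# Data-source resolution: URL parsing, transport, caching, folder catalogs.

SUPPORTED_SCHEMES <- c("file", "http", "https", "ftp", "sftp", "s3")

#' Parse a data-source locator
#'
#' Accepts local paths (no scheme, treated as `file`) and
#' `scheme://[user[:secret]@]host[:port]/path` URLs for the supported
#' schemes `file`, `http`, `https`, `ftp`, `sftp` and `s3`. Credentials
#' embedded in the authority are captured and stripped from the canonical
#' rendered form: secrets never appear in logs, error messages or cache
#' keys.
#'
#' @param text A path or URL.
#' @return A `source_url` object with fields `scheme`, `host`, `port`,
#'   `path`, `credentials`.
#' @export
#' @examples
#' parse_source_url("https://files.example.org/18037739/pbmc.h5ad")
#' parse_source_url("/data/demo.h5ad")
#' parse_source_url("s3://bucket/pbmc.h5ad")
parse_source_url <- function(text) {
  if (!is_string(text) || !nzchar(text)) {
    cd_stop("celldeck_spec_error", "source URL must be a non-empty string")
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", text)) {
    return(new_source_url("file", "", NULL, text, NULL))
  }
  scheme <- tolower(sub("://.*$", "", text))
  rest <- sub("^[A-Za-z][A-Za-z0-9+.-]*://", "", text)
  if (scheme == "irods") {
    cd_stop("celldeck_not_implemented",
            "iRODS sources are declared but not implemented")
  }
  if (!scheme %in% SUPPORTED_SCHEMES) {
    cd_stop("celldeck_unsupported_scheme", "unsupported URL scheme: %s",
            scheme)
  }
  if (scheme == "file") {
    return(new_source_url("file", "", NULL, rest, NULL))
  }
  slash <- regexpr("/", rest)
  authority <- if (slash > 0) substr(rest, 1L, slash - 1L) else rest
  path <- if (slash > 0) substr(rest, slash, nchar(rest)) else "/"
  credentials <- NULL
  at <- regexpr("@", authority)
  if (at > 0) {
    userinfo <- substr(authority, 1L, at - 1L)
    authority <- substr(authority, at + 1L, nchar(authority))
    colon <- regexpr(":", userinfo)
    credentials <- if (colon > 0) {
      list(user = substr(userinfo, 1L, colon - 1L),
           secret = substr(userinfo, colon + 1L, nchar(userinfo)))
    } else {
      list(user = userinfo, secret = "")
    }
  }
  port <- NULL
  colon <- regexpr(":", authority)
  if (colon > 0) {
    port <- as.integer(substr(authority, colon + 1L, nchar(authority)))
    authority <- substr(authority, 1L, colon - 1L)
  }
  if (!nzchar(path)) path <- "/"
  new_source_url(scheme, authority, port, path, credentials)
}

new_source_url <- function(scheme, host, port, path, credentials) {
  if (!nzchar(path)) {
    cd_stop("celldeck_spec_error", "source URL has an empty path")
  }
  structure(list(scheme = scheme, host = host, port = port, path = path,
                 credentials = credentials),
            class = "source_url")
}

#' Canonical text form of a source URL (credentials omitted)
#'
#' @param url A `source_url`.
#' @return A string; never contains credential secrets.
#' @export
render_source_url <- function(url) {
  stopifnot(inherits(url, "source_url"))
  if (url$scheme == "file") {
    return(url$path)
  }
  sprintf("%s://%s%s%s", url$scheme, url$host,
          if (!is.null(url$port)) paste0(":", url$port) else "", url$path)
}

#' @export
print.source_url <- function(x, ...) {
  cat("<source_url>", render_source_url(x),
      if (!is.null(x$credentials)) "(credentials set)" else "", "\n")
  invisible(x)
}

# default byte transport: url + destination file -> writes the bytes.
# Tests inject their own transport; s3 is mapped to virtual-host HTTPS with
# optional AWS signature-v4 signing provided by libcurl.
default_transport <- function(url, destination) {
  h <- curl::new_handle()
  target <- render_source_url(url)
  if (!is.null(url$credentials)) {
    curl::handle_setopt(h, userpwd = paste0(url$credentials$user, ":",
                                            url$credentials$secret))
  }
  if (url$scheme == "s3") {
    endpoint <- Sys.getenv("CELLDECK_S3_ENDPOINT",
                           sprintf("https://%s.s3.amazonaws.com", url$host))
    target <- paste0(endpoint, url$path)
    if (!is.null(url$credentials)) {
      curl::handle_setopt(h, aws_sigv4 = "aws:amz:us-east-1:s3",
                          username = url$credentials$user,
                          password = url$credentials$secret)
    }
  }
  curl::curl_download(target, destination, handle = h, quiet = TRUE)
  invisible(destination)
}

#' Fetch a dataset from a local or remote source
#'
#' Local `file` sources are opened directly. Remote sources are downloaded
#' once into `cache_dir`, keyed by a hash of the canonical (credential-free)
#' URL, and subsequent fetches of the same URL are served from the cache
#' without touching the transport. The cache is content-addressed by URL and
#' never invalidated: datasets are treated as immutable artifacts.
#'
#' @param url A `source_url` or a string to parse.
#' @param cache_dir Directory for cached downloads (created if needed).
#' @param transport Byte-transport function `(url, destination)`; the
#'   default handles http(s), ftp, sftp and s3 via libcurl. Tests may inject
#'   a local transport.
#' @return A `cell_dataset`.
#' @export
fetch_dataset <- function(url, cache_dir = file.path(tempdir(),
                                                     "celldeck-cache"),
                          transport = default_transport) {
  if (is.character(url)) url <- parse_source_url(url)
  stopifnot(inherits(url, "source_url"))
  if (url$scheme == "file") {
    return(load_dataset_file(url$path))
  }
  if (!dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  key <- digest::digest(render_source_url(url), algo = "sha256")
  cached <- file.path(cache_dir, paste0(key, ".h5ad"))
  if (!file.exists(cached)) {
    tmp <- paste0(cached, ".part")
    ok <- tryCatch({
      transport(url, tmp)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      unlink(tmp)
      cd_stop("celldeck_source_error", "failed to retrieve %s (%s): %s",
              render_source_url(url), url$scheme, conditionMessage(ok))
    }
    file.rename(tmp, cached)
  }
  ds <- tryCatch(load_dataset_file(cached), error = function(e) {
    unlink(cached)  # do not keep invalid bytes in the cache
    cd_stop("celldeck_format_error",
            "retrieved bytes from %s are not a valid dataset: %s",
            render_source_url(url), conditionMessage(e))
  })
  ds
}

#' List the datasets in a folder catalog
#'
#' Enumerates the `.h5ad` files directly contained in a local directory
#' (shallow, lexicographic by identifier). Each entry's title and short
#' description are read from the file's about block when possible, falling
#' back to the file stem.
#'
#' @param url A `source_url` (scheme `file`) or directory path.
#' @return A `dataset_catalog`: data frame with columns `id`, `source`,
#'   `title`, `short`.
#' @export
list_catalog <- function(url) {
  if (is.character(url)) url <- parse_source_url(url)
  stopifnot(inherits(url, "source_url"))
  if (url$scheme != "file") {
    cd_stop("celldeck_source_error",
            "catalog listing is only supported for local folders (got %s)",
            url$scheme)
  }
  if (!dir.exists(url$path)) {
    cd_stop("celldeck_source_error", "not a listable directory: %s",
            url$path)
  }
  files <- sort(list.files(url$path, pattern = "\\.h5ad$",
                           full.names = TRUE))
  entries <- lapply(files, function(f) {
    stem <- sub("\\.h5ad$", "", basename(f))
    title <- stem
    short <- ""
    about <- tryCatch({
      list(title = as.character(rhdf5::h5read(f, "/uns/about/title")),
           short = as.character(rhdf5::h5read(f, "/uns/about/short")))
    }, error = function(e) NULL)
    if (!is.null(about)) {
      if (is_string(about$title) && nzchar(about$title)) title <- about$title
      if (is_string(about$short)) short <- about$short
    }
    data.frame(id = stem, source = f, title = title, short = short,
               stringsAsFactors = FALSE)
  })
  out <- if (length(entries)) {
    do.call(rbind, entries)
  } else {
    data.frame(id = character(), source = character(), title = character(),
               short = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dataset_catalog", "data.frame")
  out
}
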