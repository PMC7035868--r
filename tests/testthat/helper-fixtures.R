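# shared fixtures and independent oracles used across the suite

# 3 cells x 2 genes, counts [[1,0],[0,2],[3,0]]
tiny_dataset <- function() {
  cell_dataset(
    counts = matrix(c(1, 0, 0, 2, 3, 0), nrow = 3, byrow = TRUE),
    cell_table = data.frame(cell_id = c("AAAC-1", "AAAG-1", "AACA-1")),
    gene_table = data.frame(gene_id = c("ENSG1", "ENSG2"),
                            symbol = c("ACTB", "GAPDH")),
    about = list(title = "tiny", short = "3x2 test dataset"))
}

# randomized small dataset for property tests, deterministic in `seed`
random_dataset <- function(seed, condition = FALSE) {
  dims <- with_test_seed(seed, list(
    n_cells = sample(30:80, 1), n_genes = sample(40:120, 1),
    k = sample(2:4, 1)))
  generate_clustered_dataset(sim_spec(
    n_cells = dims$n_cells, n_genes = dims$n_genes, k_clusters = dims$k,
    de_genes_per_cluster = 5L,
    condition_fraction = if (condition) 0.5 else NULL,
    seed = seed))$dataset
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- independent oracles ---------------------------------------------------

# exact two-sided rank-sum p by exhaustive enumeration of all C(m+n, m)
# assignments of the pooled ranks to group 1 (no ties assumed)
ranksum_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(pooled), n1)
  us <- apply(assignments, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(y) / 2
  # two-sided: as extreme or more extreme in |U - mn/2|
  mean(abs(us - mu) >= abs(obs_u - mu) - 1e-9)
}

# tie-corrected normal approximation, no continuity correction
ranksum_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# literal step-up BH, written independently of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# winding-number point-in-polygon (angle summation)
winding_oracle <- function(points, polygon) {
  apply(points, 1, function(p) {
    dx <- polygon[, 1] - p[1]
    dy <- polygon[, 2] - p[2]
    nxt <- c(seq_len(nrow(polygon))[-1], 1L)
    total <- sum(atan2(
      dx * dy[nxt] - dy * dx[nxt],
      dx * dx[nxt] + dy * dy[nxt]))
    abs(total) > 1e-6
  })
}

# random convex polygon: convex hull of random points
random_convex_polygon <- function(n_pts = 8) {
  pts <- matrix(stats::runif(2 * n_pts, -5, 5), ncol = 2)
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

# --- in-process HTTP helpers ----------------------------------------------

# perform one HTTP request against an httpuv server running in this process
# by pumping the httpuv event loop while curl's multi interface polls
pump_request <- function(url, body = NULL, timeout = 20) {
  h <- curl::new_handle(url = url)
  if (!is.null(body)) {
    curl::handle_setopt(h, postfields = body)
    curl::handle_setheaders(h, "Content-Type" = "application/json")
  }
  out <- NULL
  err <- NULL
  curl::multi_add(h, done = function(res) out <<- res,
                  fail = function(e) err <<- e)
  t0 <- Sys.time()
  while (is.null(out) && is.null(err) &&
         as.numeric(Sys.time() - t0, units = "secs") < timeout) {
    curl::multi_run(timeout = 0)
    httpuv::service(25)
  }
  if (!is.null(err)) stop(err)
  if (is.null(out)) stop("in-process HTTP request timed out")
  list(status = out$status_code, content = out$content,
       text = tryCatch(rawToChar(out$content),
                       error = function(e) NA_character_),
       type = out$type)
}

# a local HTTP file server with a request counter (for cache tests)
counting_file_server <- function(dir) {
  env <- new.env()
  env$count <- 0L
  srv <- httpuv::startServer("127.0.0.1", httpuv::randomPort(), list(
    call = function(req) {
      env$count <- env$count + 1L
      f <- file.path(dir, sub("^/", "", req$PATH_INFO))
      if (!file.exists(f)) {
        return(list(status = 404L, headers = list("Content-Type" = "text/plain"),
                    body = "not found"))
      }
      list(status = 200L,
           headers = list("Content-Type" = "application/octet-stream"),
           body = readBin(f, "raw", file.info(f)$size))
    }))
  env$url <- sprintf("http://127.0.0.1:%d", srv$getPort())
  env$server <- srv
  env
}

# transport usable against an in-process server (curl_download would block
# the event loop); fails on HTTP errors like a real transport
pump_transport <- function(url, destination) {
  res <- pump_request(render_source_url(url))
  if (res$status >= 400) stop(sprintf("HTTP %d", res$status))
  writeBin(res$content, destination)
  invisible(destination)
}
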