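test_that("cli_convert detects formats, writes h5ad and reports", {
  dir <- withr::local_tempdir()
  ds <- generate_clustered_dataset(sim_spec(n_cells = 30, n_genes = 25,
                                            seed = 14))$dataset
  ds$markers <- ds$markers[0, ]
  write_cellranger_fixture(ds, file.path(dir, "cr"))
  out <- file.path(dir, "out.h5ad")
  report <- suppressWarnings(capture.output(
    rep <- cli_convert(file.path(dir, "cr"), out)))
  expect_true(file.exists(out))
  expect_equal(rep$n_cells, 30)
  expect_equal(rep$n_genes, 25)
  expect_equal(rep$source_format, "cellranger")
  expect_match(report[1], "30 cells x 25 genes")
  reloaded <- suppressWarnings(load_dataset_file(out))
  expect_true(all(reloaded$counts == ds$counts))

  # loom dispatch by extension
  write_loom_fixture(ds, file.path(dir, "d.loom"))
  capture.output(rep2 <- cli_convert(file.path(dir, "d.loom"),
                                     file.path(dir, "out2.h5ad")))
  expect_equal(rep2$source_format, "loom")

  # text needs two inputs
  write_text_fixture(ds, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  capture.output(rep3 <- cli_convert(c(file.path(dir, "m.tsv"),
                                       file.path(dir, "a.tsv")),
                                     file.path(dir, "out3.h5ad")))
  expect_equal(rep3$source_format, "text")

  expect_error(cli_convert(file.path(dir, "nothing.xyz"),
                           file.path(dir, "out4.h5ad")),
               class = "celldeck_spec_error")
})

test_that("about metadata files are applied during conversion", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  write_cellranger_fixture(ds, file.path(dir, "cr"))
  about <- file.path(dir, "about.json")
  writeLines('{"title": "My sample", "short": "demo"}', about)
  out <- file.path(dir, "with-about.h5ad")
  capture.output(cli_convert(file.path(dir, "cr"), out,
                             about_file = about))
  loaded <- suppressWarnings(load_dataset_file(out))
  expect_equal(loaded$about$title, "My sample")
  expect_equal(loaded$about$short, "demo")
})

test_that("app_config validates sources and reads the environment", {
  expect_error(app_config(), class = "celldeck_spec_error")
  expect_error(app_config(data_sources = "/x", port = 99999),
               class = "celldeck_spec_error")
  withr::local_envvar(CELLDECK_DATA_SOURCES = "/a.h5ad;/b.h5ad")
  cfg <- app_config()
  expect_equal(cfg$data_sources, c("/a.h5ad", "/b.h5ad"))
  # explicit arguments win over the environment
  cfg2 <- app_config(data_sources = "/c.h5ad")
  expect_equal(cfg2$data_sources, "/c.h5ad")
})

with_test_server <- function(dir, code, upload_enabled = FALSE) {
  config <- app_config(data_sources = dir,
                       cache_dir = file.path(dir, "cache"),
                       port = httpuv::randomPort(),
                       upload_enabled = upload_enabled)
  server <- run_server(config, blocking = FALSE)
  on.exit(httpuv::stopServer(server))
  base <- sprintf("http://127.0.0.1:%d", config$port)
  force(code)(base)
}

test_that("the service serves catalog, about and library-equal payloads", {
  dir <- withr::local_tempdir()
  sim <- generate_clustered_dataset(sim_spec(n_cells = 80, n_genes = 60,
                                             k_clusters = 2,
                                             condition_fraction = 0.5,
                                             seed = 15))
  ds <- sim$dataset
  save_dataset(ds, file.path(dir, "demo.h5ad"))

  with_test_server(dir, function(base) {
    cat_res <- pump_request(paste0(base, "/api/catalog"))
    expect_equal(cat_res$status, 200)
    cat_json <- jsonlite::fromJSON(cat_res$text, simplifyVector = FALSE)
    expect_length(cat_json$datasets, 1)
    expect_equal(cat_json$datasets[[1]]$id, "demo")

    about <- jsonlite::fromJSON(
      pump_request(paste0(base, "/api/dataset/demo/about"))$text)
    expect_equal(about$title, ds$about$title)
    expect_equal(about$long, ds$about$long)

    meta <- jsonlite::fromJSON(
      pump_request(paste0(base, "/api/dataset/demo/meta"))$text,
      simplifyVector = FALSE)
    expect_equal(meta$n_cells, n_cells(ds))
    expect_equal(unlist(meta$embeddings), "tsne")

    # filter endpoint equals the library call
    spec <- filter_spec(filter_categorical("cluster", "1"))
    body <- sprintf('{"filters": %s}', filter_spec_to_json(spec))
    flt <- jsonlite::fromJSON(
      pump_request(paste0(base, "/api/dataset/demo/filter"), body)$text)
    expect_identical(as.integer(flt$cells), apply_filter(ds, spec))

    # differential expression payload is byte-equal to the library TSV
    a <- which(ds$cell_table$cluster == "1")
    b <- which(ds$cell_table$cluster == "2")
    body <- as.character(jsonlite::toJSON(
      list(groups = list(A = a, B = b)), auto_unbox = TRUE))
    served <- pump_request(paste0(base, "/api/dataset/demo/diffexp"),
                           body)
    direct <- diffexp_to_tsv(
      differential_expression(ds, list(A = a, B = b)))
    expect_identical(served$text, direct)
    expect_match(served$type, "tab-separated")

    # dot plot payload equality
    genes <- ds$gene_table$symbol[1:4]
    body <- as.character(jsonlite::toJSON(
      list(genes = genes, group_by = "cluster", split_by = "condition"),
      auto_unbox = TRUE))
    served <- pump_request(paste0(base, "/api/dataset/demo/dotplot"), body)
    direct <- format_tsv(dot_plot_summary(ds, genes, "cluster",
                                          split_by = "condition"))
    expect_identical(served$text, direct)

    # composition payload equality
    body <- '{"primary": "cluster", "secondary": "condition"}'
    served <- pump_request(paste0(base, "/api/dataset/demo/composition"),
                           body)
    expect_identical(served$text,
                     format_tsv(composition_table(ds, "cluster",
                                                  "condition")))

    # errors surface as JSON with a 4xx status
    bad <- pump_request(paste0(base, "/api/dataset/nope/about"))
    expect_equal(bad$status, 400)
    expect_match(bad$text, "unknown dataset")
    missing <- pump_request(paste0(base, "/api/no/such/route"))
    expect_equal(missing$status, 404)
  })
})

test_that("repeated service requests are identical (stateless views)", {
  dir <- withr::local_tempdir()
  save_dataset(random_dataset(16), file.path(dir, "d.h5ad"))
  with_test_server(dir, function(base) {
    body <- '{"value": "GENE001", "group_by": "cluster"}'
    one <- pump_request(paste0(base, "/api/dataset/d/distribution"), body)
    two <- pump_request(paste0(base, "/api/dataset/d/distribution"), body)
    expect_identical(one$text, two$text)
  })
})

test_that("uploads add validated datasets to the catalog", {
  dir <- withr::local_tempdir()
  save_dataset(random_dataset(17), file.path(dir, "seed.h5ad"))
  uploaded <- random_dataset(18)
  up_path <- file.path(dir, "up.h5ad")
  save_dataset(uploaded, up_path)
  payload <- readBin(up_path, "raw", file.info(up_path)$size)
  unlink(up_path)

  with_test_server(dir, function(base) {
    h <- curl::new_handle(url = paste0(base, "/api/upload"))
    curl::handle_setopt(h, postfields = payload)
    out <- NULL
    curl::multi_add(h, done = function(res) out <<- res,
                    fail = function(e) stop(e))
    while (is.null(out)) {
      curl::multi_run(timeout = 0)
      httpuv::service(25)
    }
    res <- jsonlite::fromJSON(rawToChar(out$content))
    expect_match(res$id, "^upload-")
    cat_json <- jsonlite::fromJSON(
      pump_request(paste0(base, "/api/catalog"))$text,
      simplifyVector = FALSE)
    ids <- vapply(cat_json$datasets, `[[`, "", "id")
    expect_true(res$id %in% ids)
    served_about <- jsonlite::fromJSON(pump_request(
      paste0(base, "/api/dataset/", res$id, "/about"))$text)
    expect_equal(served_about$title, uploaded$about$title)
  }, upload_enabled = TRUE)
})

test_that("uploads are rejected when disabled", {
  dir <- withr::local_tempdir()
  save_dataset(random_dataset(19), file.path(dir, "d.h5ad"))
  with_test_server(dir, function(base) {
    res <- pump_request(paste0(base, "/api/upload"), body = "zzz")
    expect_equal(res$status, 403)
  })
})
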