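test_that("CellRanger fixture round-trips counts bit-exact", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  fx <- file.path(dir, "cr")
  write_cellranger_fixture(ds, fx)
  res <- convert_cellranger(fx, about = ds$about)
  expect_true(all(res$dataset$counts == ds$counts))
  expect_equal(res$report$n_cells, 3)
  expect_equal(res$report$n_genes, 2)
  expect_equal(res$report$source_format, "cellranger")
  expect_identical(res$dataset$cell_table$cell_id, ds$cell_table$cell_id)
  expect_identical(res$dataset$gene_table$symbol, ds$gene_table$symbol)
})

test_that("gzipped CellRanger input yields an identical dataset", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  write_cellranger_fixture(ds, file.path(dir, "plain"))
  write_cellranger_fixture(ds, file.path(dir, "gz"), gzip = TRUE)
  a <- convert_cellranger(file.path(dir, "plain"))$dataset
  b <- convert_cellranger(file.path(dir, "gz"))$dataset
  a$about <- b$about <- NULL
  expect_identical(dataset_differences(a, b), character(0))
})

test_that("missing CellRanger files produce a format error naming them", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty")
  dir.create(empty)
  expect_error(convert_cellranger(empty), "matrix.mtx",
               class = "celldeck_format_error")
  expect_error(convert_cellranger(file.path(dir, "nowhere")),
               class = "celldeck_io_error")
})

test_that("barcode/feature count mismatches are consistency errors", {
  dir <- withr::local_tempdir()
  fx <- file.path(dir, "cr")
  write_cellranger_fixture(tiny_dataset(), fx)
  # drop one barcode
  bl <- readLines(file.path(fx, "barcodes.tsv"))
  writeLines(bl[-1], file.path(fx, "barcodes.tsv"))
  expect_error(convert_cellranger(fx), "does not match",
               class = "celldeck_format_error")
})

test_that("a CellRanger analysis directory contributes cluster, embedding and markers", {
  dir <- withr::local_tempdir()
  fx <- file.path(dir, "cr")
  ds <- tiny_dataset()
  write_cellranger_fixture(ds, fx)
  cldir <- file.path(fx, "analysis", "clustering", "graphclust")
  prdir <- file.path(fx, "analysis", "tsne", "2_components")
  dir.create(cldir, recursive = TRUE)
  dir.create(prdir, recursive = TRUE)
  write.csv(data.frame(Barcode = ds$cell_table$cell_id,
                       Cluster = c(1, 2, 1)),
            file.path(cldir, "clusters.csv"), row.names = FALSE)
  write.csv(data.frame(Barcode = ds$cell_table$cell_id,
                       TSNE.1 = c(0.5, -1, 2), TSNE.2 = c(1, 0, -2)),
            file.path(prdir, "projection.csv"), row.names = FALSE)
  out <- convert_cellranger(fx)$dataset
  expect_identical(as.character(out$cell_table$cluster), c("1", "2", "1"))
  expect_equal(out$embeddings$tsne[, 1], c(0.5, -1, 2))
  # a second clustering makes resolution ambiguous
  cldir2 <- file.path(fx, "analysis", "clustering", "kmeans_2")
  dir.create(cldir2, recursive = TRUE)
  file.copy(file.path(cldir, "clusters.csv"), cldir2)
  unlink(file.path(cldir), recursive = TRUE)
  dir.create(file.path(fx, "analysis", "clustering", "kmeans_3"),
             recursive = TRUE)
  file.copy(file.path(cldir2, "clusters.csv"),
            file.path(fx, "analysis", "clustering", "kmeans_3"))
  expect_error(convert_cellranger(fx), "ambiguous",
               class = "celldeck_format_error")
})

test_that("loom fixtures round-trip through convert_loom", {
  dir <- withr::local_tempdir()
  src <- generate_clustered_dataset(sim_spec(n_cells = 40, n_genes = 60,
                                             k_clusters = 2, seed = 9))
  ds <- src$dataset
  ds$markers <- ds$markers[0, ]  # loom carries no marker table
  loom <- file.path(dir, "rt.loom")
  write_loom_fixture(ds, loom)
  out <- convert_loom(loom, about = ds$about)$dataset
  expect_identical(dataset_differences(ds, out), character(0))
  expect_true(all(out$counts == ds$counts))
  # embedding reassembled from tsne_X / tsne_Y column attributes
  expect_named(out$embeddings, "tsne")
  expect_equal(out$embeddings$tsne, ds$embeddings$tsne)
})

test_that("degenerate loom inputs fail with format errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.loom")
  rhdf5::h5createFile(f)
  rhdf5::h5write(matrix(numeric(0), 0, 0), f, "matrix")
  expect_error(convert_loom(f), "empty dataset",
               class = "celldeck_format_error")
  g <- file.path(dir, "nomatrix.loom")
  rhdf5::h5createFile(g)
  rhdf5::h5write(1:3, g, "other")
  expect_error(convert_loom(g), "matrix", class = "celldeck_format_error")
  txt <- file.path(dir, "fake.loom")
  writeLines("nope", txt)
  expect_error(convert_loom(txt), class = "celldeck_format_error")
})

test_that("text conversion aligns cells and types annotation columns", {
  dir <- withr::local_tempdir()
  mfile <- file.path(dir, "expr.tsv")
  afile <- file.path(dir, "annot.tsv")
  writeLines(c("symbol\tc1\tc2\tc3",
               "ACTB\t1\t0\t3",
               "GAPDH\t0\t2\t0"), mfile)
  writeLines(c("cell_id\tgroup\tdepth",
               "c1\tx\t100",
               "c2\ty\t200",
               "c3\tx\t300"), afile)
  res <- convert_text(mfile, afile)
  expect_equal(res$report$n_cells, 3)
  expect_equal(res$report$n_genes, 2)
  expect_length(res$report$warnings, 0)
  expect_true(all(res$dataset$counts ==
                    matrix(c(1, 0, 0, 2, 3, 0), nrow = 3, byrow = TRUE)))
  expect_s3_class(res$dataset$cell_table$group, "factor")
  # few distinct numeric values look cluster-like by default ...
  expect_s3_class(res$dataset$cell_table$depth, "factor")
  # ... and stay numeric when the heuristic is tightened
  res2 <- convert_text(mfile, afile, max_factor_levels = 2)
  expect_type(res2$dataset$cell_table$depth, "double")
  expect_s3_class(res2$dataset$cell_table$group, "factor")
})

test_that("extra annotation cells are dropped with a warning", {
  dir <- withr::local_tempdir()
  mfile <- file.path(dir, "expr.csv")
  afile <- file.path(dir, "annot.csv")
  writeLines(c("symbol,c1,c2", "ACTB,1,2"), mfile)
  writeLines(c("cell_id,group", "c1,x", "c2,y", "c9,z"), afile)
  res <- convert_text(mfile, afile)
  expect_equal(res$report$n_cells, 2)
  expect_length(res$report$warnings, 1)
  expect_match(res$report$warnings, "1 cell")
})

test_that("duplicated gene symbols are de-duplicated with suffixes", {
  dir <- withr::local_tempdir()
  mfile <- file.path(dir, "expr.tsv")
  afile <- file.path(dir, "annot.tsv")
  writeLines(c("symbol\tc1\tc2", "MT-CO1\t1\t2", "MT-CO1\t3\t4"), mfile)
  writeLines(c("cell_id\tgroup", "c1\tx", "c2\ty"), afile)
  res <- convert_text(mfile, afile)
  expect_identical(res$dataset$gene_table$symbol, c("MT-CO1", "MT-CO1.1"))
  expect_match(res$report$warnings, "de-duplicated")
  expect_error(convert_text(mfile, file.path(dir, "nope.tsv")),
               class = "celldeck_io_error")
})

test_that("zero overlapping identifiers is a consistency error", {
  dir <- withr::local_tempdir()
  mfile <- file.path(dir, "expr.tsv")
  afile <- file.path(dir, "annot.tsv")
  writeLines(c("symbol\tc1", "ACTB\t1"), mfile)
  writeLines(c("cell_id\tgroup", "zz\tx"), afile)
  expect_error(convert_text(mfile, afile), "overlapping",
               class = "celldeck_format_error")
})

test_that("the same data converts identically from all three formats", {
  dir <- withr::local_tempdir()
  # gene_id == symbol because raw text carries no separate identifier
  counts <- matrix(c(4, 0, 1, 2, 0, 5, 3, 1), nrow = 4)
  ds <- cell_dataset(
    counts = counts,
    cell_table = data.frame(cell_id = sprintf("c%d", 1:4),
                            grp = factor(c("a", "a", "b", "b"))),
    gene_table = data.frame(gene_id = c("ACTB", "GAPDH"),
                            symbol = c("ACTB", "GAPDH")),
    embeddings = list(tsne = cbind(as.numeric(1:4), as.numeric(4:1))),
    about = list(title = "fmt"))
  write_cellranger_fixture(ds, file.path(dir, "cr"))
  write_loom_fixture(ds, file.path(dir, "d.loom"))
  write_text_fixture(ds, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  cr <- convert_cellranger(file.path(dir, "cr"), about = ds$about)$dataset
  lo <- convert_loom(file.path(dir, "d.loom"), about = ds$about)$dataset
  tx <- convert_text(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"),
                     about = ds$about)$dataset
  expect_true(all(cr$counts == ds$counts))
  expect_true(all(lo$counts == ds$counts))
  expect_true(all(tx$counts == ds$counts))
  # loom and text carry annotation + embeddings; they agree with the source
  expect_identical(dataset_differences(lo, tx), character(0))
})
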