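four_cell_dataset <- function() {
  # normalized values chosen by hand: gene EXPR is (0, 2 | 1, 3) over A, B
  norm <- cbind(EXPR = c(0, 2, 1, 3), ZERO = c(0, 0, 0, 0))
  cell_dataset(
    normalized = norm,
    cell_table = data.frame(cell_id = sprintf("c%d", 1:4),
                            grp = factor(c("A", "A", "B", "B")),
                            cond = factor(c("ctrl", "stim", "ctrl",
                                            "stim"))),
    gene_table = data.frame(gene_id = c("e1", "e2"),
                            symbol = c("EXPR", "ZERO")))
}

test_that("dot-plot means and expressing fractions are exact on a hand fixture", {
  ds <- four_cell_dataset()
  out <- dot_plot_summary(ds, c("EXPR", "ZERO"), group_by = "grp")
  expr <- out[out$gene == "EXPR", ]
  expect_equal(expr$mean[expr$group == "A"], 1)    # mean(0, 2), zeros included
  expect_equal(expr$mean[expr$group == "B"], 2)    # mean(1, 3)
  expect_equal(expr$fraction[expr$group == "A"], 0.5)
  expect_equal(expr$fraction[expr$group == "B"], 1)
  zero <- out[out$gene == "ZERO", ]
  expect_true(all(zero$mean == 0))
  expect_true(all(zero$fraction == 0))
})

test_that("split dot plots enumerate observed combinations only", {
  ds <- four_cell_dataset()
  out <- dot_plot_summary(ds, "EXPR", group_by = "grp", split_by = "cond")
  expect_equal(nrow(out), 4)  # all 4 (grp, cond) pairs occupied
  expect_setequal(paste(out$group, out$split),
                  c("A ctrl", "A stim", "B ctrl", "B stim"))
  # restricting cells drops empty combinations instead of zero-filling
  sub <- dot_plot_summary(ds, "EXPR", group_by = "grp", split_by = "cond",
                          cells = c(1, 3, 4))
  expect_equal(nrow(sub), 3)
  expect_error(dot_plot_summary(ds, c("EXPR", "NOPE1", "NOPE2"), "grp"),
               "NOPE1, NOPE2", class = "celldeck_spec_error")
  expect_error(dot_plot_summary(ds, "EXPR", group_by = "cell_id"),
               class = "celldeck_spec_error")
})

test_that("composition tables tally counts and within-level proportions", {
  ds <- cell_dataset(
    normalized = matrix(0, 6, 1),
    cell_table = data.frame(
      cell_id = sprintf("c%d", 1:6),
      cluster = factor(c("c1", "c1", "c1", "c2", "c2", "c2")),
      species = factor(c("human", "human", "mouse", "mouse", "mouse",
                         "mouse"))),
    gene_table = data.frame(gene_id = "g", symbol = "G"))
  out <- composition_table(ds, "cluster", "species")
  get <- function(p, s, col) out[out$primary == p & out$secondary == s, col]
  expect_equal(get("c1", "human", "proportion"), 2 / 3)
  expect_equal(get("c1", "mouse", "proportion"), 1 / 3)
  expect_equal(get("c2", "human", "proportion"), 0)
  expect_equal(get("c2", "mouse", "proportion"), 1)
  expect_equal(sum(out$n), 6)
  # per-primary proportions sum to one
  for (p in c("c1", "c2")) {
    expect_equal(sum(out$proportion[out$primary == p]), 1,
                 tolerance = 1e-12)
  }
  # empty subset: counts 0, proportions flagged undefined
  none <- composition_table(ds, "cluster", "species", cells = integer())
  expect_true(all(none$n == 0))
  expect_true(all(none$proportion == 0))
  expect_true(all(!none$defined))
  # a cluster whose cells are all one species
  pure <- composition_table(ds, "cluster", "species", cells = 4:6)
  expect_equal(pure[pure$primary == "c2" & pure$secondary == "mouse",
                    "proportion"], 1)
})

test_that("species-mix calls follow the purity threshold", {
  pure <- species_mix_stats(100, 0)
  expect_equal(as.character(pure$per_cell$call), "species1")
  balanced <- species_mix_stats(50, 50)
  expect_equal(as.character(balanced$per_cell$call), "doublet")
  expect_equal(species_mix_stats(c(95, 5), c(5, 95))$doublet_rate, 0)
  expect_error(species_mix_stats(c(1, 0), c(1, 0)),
               class = "celldeck_domain_error")
  expect_error(species_mix_stats(1:3, 1:2), class = "celldeck_spec_error")
})

test_that("simulated barnyard mixtures recover the planted doublet rate", {
  mix <- generate_species_mix(1000, doublet_rate = 0.02, mean_umis = 1000,
                              seed = 5)
  stats <- species_mix_stats(mix$h, mix$m)
  # estimate within the exact binomial 95% interval around 0.02
  test <- stats::binom.test(stats$n_doublet, 1000, p = 0.02)
  expect_gt(test$p.value, 0.05)
  # with clean separation the calls match the planted truth
  expect_equal(as.character(stats$per_cell$call),
               as.character(mix$true_call))
})

test_that("distribution panels compute interpolated quartiles per group", {
  norm <- cbind(VAL = c(1, 2, 3, 4, 9))
  ds <- cell_dataset(
    normalized = norm,
    cell_table = data.frame(cell_id = sprintf("c%d", 1:5),
                            grp = factor(c("a", "a", "a", "a", "b")),
                            VALCOL = c(5, 6, 7, 8, 9)),
    gene_table = data.frame(gene_id = "v", symbol = "VAL"))
  out <- distribution_panel(ds, "VAL", "grp")
  a <- out$summary[out$summary$group == "a", ]
  expect_equal(a$median, 2.5)
  expect_equal(a$q1, 1.75)
  expect_equal(a$q3, 3.25)
  b <- out$summary[out$summary$group == "b", ]  # singleton group
  expect_equal(unname(unlist(b[c("median", "q1", "q3")])), c(9, 9, 9))
  expect_equal(out$values$a, c(1, 2, 3, 4))
  # numeric columns resolve too
  col <- distribution_panel(ds, "VALCOL", "grp")
  expect_equal(col$values$b, 9)
  expect_error(distribution_panel(ds, "nope", "grp"),
               class = "celldeck_spec_error")
})

test_that("gene/column name collisions require qualification", {
  norm <- cbind(AMBIG = c(0, 1, 2, 3))
  ds <- cell_dataset(
    normalized = norm,
    cell_table = data.frame(cell_id = sprintf("c%d", 1:4),
                            grp = factor(rep("g", 4)),
                            AMBIG = c(10, 20, 30, 40)),
    gene_table = data.frame(gene_id = "a", symbol = "AMBIG"))
  expect_error(distribution_panel(ds, "AMBIG", "grp"), "both",
               class = "celldeck_spec_error")
  as_gene <- distribution_panel(ds, "gene:AMBIG", "grp")
  as_col <- distribution_panel(ds, "column:AMBIG", "grp")
  expect_equal(as_gene$values$g, c(0, 1, 2, 3))
  expect_equal(as_col$values$g, c(10, 20, 30, 40))
})

test_that("downsampling is an identity below the cap and uniform above it", {
  expect_identical(downsample_cells(100, 200), 1:100)
  once <- downsample_cells(1000, 100, seed = 3)
  again <- downsample_cells(1000, 100, seed = 3)
  expect_identical(once, again)
  expect_length(once, 100)
  # uniformity: per-cell inclusion frequency across 50 seeds
  n <- 2000; keep <- 200
  freq <- rowMeans(vapply(1:50, function(s) {
    seq_len(n) %in% downsample_cells(n, keep, seed = s)
  }, logical(n)))
  p <- keep / n
  se <- sqrt(p * (1 - p) / 50)
  outliers <- mean(abs(freq - p) > 3 * se)
  expect_lt(outliers, 0.01)  # ~0.3% expected by chance
  expect_error(downsample_cells(10, 0), class = "celldeck_spec_error")
})

test_that("summaries on a cell subset match the physically subset dataset", {
  with_test_seed(19, {
    for (trial in 1:5) {
      ds <- random_dataset(trial + 200, condition = TRUE)
      cells <- sort(sample(n_cells(ds), ceiling(n_cells(ds) * 0.6)))
      sub <- subset_cells(ds, cells)
      genes <- ds$gene_table$symbol[1:3]

      a <- dot_plot_summary(ds, genes, "cluster", split_by = "condition",
                            cells = cells)
      b <- dot_plot_summary(sub, genes, "cluster", split_by = "condition")
      expect_equal(a, b)

      a <- composition_table(ds, "cluster", "condition", cells = cells)
      b <- composition_table(sub, "cluster", "condition")
      expect_equal(a, b)

      a <- distribution_panel(ds, genes[1], "cluster", cells = cells)
      b <- distribution_panel(sub, genes[1], "cluster")
      expect_equal(a, b)
    }
  })
})
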