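test_that("DE thresholds are strict on both fold change and p-value", {
  rec <- tibble::tibble(
    gene_id = c("fc_exact", "up", "p_exact", "down"),
    log2fc = c(log2(1.5), 1.0, -0.7, -1.2),
    pvalue = c(0.01, 0.049, 0.05, 0.001)
  )
  out <- threshold_de(rec)
  de <- stats::setNames(out$de, out$gene_id)
  expect_false(de[["fc_exact"]])  # |FC| must exceed 1.5
  expect_true(de[["up"]])
  expect_false(de[["p_exact"]])   # p must be below 0.05
  expect_true(de[["down"]])
  expect_equal(out$direction[out$gene_id == "up"], "up")
  expect_equal(out$direction[out$gene_id == "down"], "down")
})

test_that("missing statistics are excluded with a warning; relaxing thresholds is monotone", {
  rec <- tibble::tibble(gene_id = c("ok", "bad"),
                        log2fc = c(2, NaN), pvalue = c(0.01, 0.5))
  expect_warning(out <- threshold_de(rec), "excluding")
  expect_equal(out$gene_id, "ok")

  set.seed(3)
  rec2 <- tibble::tibble(gene_id = paste0("g", 1:300),
                         log2fc = stats::rnorm(300, 0, 1.2),
                         pvalue = stats::runif(300))
  strict <- threshold_de(rec2)
  relaxed_fc <- threshold_de(rec2, de_config(min_abs_fc = 1.2))
  relaxed_p <- threshold_de(rec2, de_config(max_pvalue = 0.2))
  expect_true(all(strict$gene_id[strict$de] %in% relaxed_fc$gene_id[relaxed_fc$de]))
  expect_true(all(strict$gene_id[strict$de] %in% relaxed_p$gene_id[relaxed_p$de]))
})

test_that("Fisher's exact p matches the worked enumerations exactly", {
  expect_equal(fisher_exact_2x2(0, 5, 0, 5), 1.0)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher's exact p agrees with stats::fisher.test on random tables", {
  set.seed(17)
  for (i in 1:60) {
    cells <- stats::rpois(4, sample(c(2, 8, 25), 1))
    if (sum(cells) == 0) cells[1] <- 1
    p_pkg <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10,
                 info = paste(cells, collapse = ","))
  }
})

test_that("proportion enrichment builds the right table and fractions", {
  bg <- paste0("g", 1:100)
  fg <- bg[1:20]
  res <- proportion_enrichment(fg, fg, bg)   # subset == foreground
  expect_equal(res$fraction_foreground, 1.0)
  expect_equal(unname(res$table["foreground", "in_subset"]), 20)

  sub <- bg[c(1:10, 21:40)]
  res2 <- proportion_enrichment(sub, fg, bg)
  expect_equal(res2$fraction_foreground, 0.5)
  expect_equal(res2$fraction_background, 0.3)
  expect_error(proportion_enrichment(sub, character(), bg), "empty")
  expect_error(proportion_enrichment(sub, c(fg, "zzz"), bg), "subset of")
})

test_that("a uniformly distributed subset is not called enriched", {
  set.seed(5)
  bg <- paste0("g", 1:400)
  fg <- bg[1:200]
  p_vals <- replicate(200, proportion_enrichment(sample(bg, 100), fg, bg)$p_value)
  expect_gt(stats::median(p_vals), 0.4)
})

test_that("a planted 2x over-representation is detected with high power", {
  set.seed(6)
  bg <- paste0("g", 1:600)
  fg <- bg[1:150]
  hits <- 0L
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    # subset drawn with 2x the inclusion rate inside the foreground
    sub <- c(sample(fg, 60), sample(setdiff(bg, fg), 90))
    if (proportion_enrichment(sub, fg, bg)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("hierarchical clustering separates planted profile archetypes", {
  set.seed(9)
  up <- matrix(rep(c(0, 0, 5, 5), each = 15), nrow = 15) +
    stats::rnorm(60, 0, 0.1)
  down <- matrix(rep(c(5, 5, 0, 0), each = 15), nrow = 15) +
    stats::rnorm(60, 0, 0.1)
  m <- rbind(up, down)
  rownames(m) <- paste0("g", 1:30)
  colnames(m) <- paste0("c", 1:4)
  cl <- cluster_de_genes(m, 2)
  expect_equal(length(unique(cl$cluster[1:15])), 1L)
  expect_equal(length(unique(cl$cluster[16:30])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[16])

  expect_error(cluster_de_genes(m[1:3, ], 6), "fewer genes")

  # identical rows: the cut still returns k labels, with a warning
  flat <- matrix(1, nrow = 8, ncol = 4,
                 dimnames = list(paste0("f", 1:8), paste0("c", 1:4)))
  expect_warning(cl_flat <- cluster_de_genes(flat, 3), "zero-variance")
  expect_equal(sort(unique(cl_flat$cluster)), 1:3)

  # permuting condition labels leaves the partition intact
  cl_perm <- cluster_de_genes(m[, c(3, 4, 1, 2)], 2)
  expect_equal(cl$cluster, cl_perm$cluster)
})

test_that("the plain two-group DE summary behaves on planted shifts", {
  set.seed(10)
  n <- 40
  vals <- matrix(stats::rlnorm(n * 10, 1, 0.2), nrow = n,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:10)))
  vals[1:5, 6:10] <- vals[1:5, 6:10] * 4   # planted 4-fold induction
  cond <- stats::setNames(rep(c("A", "B"), each = 5), colnames(vals))
  em <- expression_matrix(vals, cond)
  de <- simple_de_stub(em, "A", "B")
  expect_equal(attr(de, "method"), "welch_log2")
  expect_true(all(de$log2fc[1:5] > 1))
  expect_true(all(de$pvalue[1:5] < 0.05))

  # identical groups: log2fc 0 for every gene
  dup <- cbind(vals[, 1:5], vals[, 1:5])
  colnames(dup) <- c(paste0("s", 1:5), paste0("r", 1:5))
  same <- expression_matrix(dup, stats::setNames(rep(c("A", "B"), each = 5),
                                                 colnames(dup)))
  de_same <- simple_de_stub(same, "A", "B")
  expect_equal(de_same$log2fc, rep(0, n))
  expect_true(all(de_same$pvalue == 1))
})
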