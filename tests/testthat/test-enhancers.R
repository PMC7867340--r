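elnc_genes_fixture <- function() {
  tibble::tibble(
    gene_id = c("lnc_over", "lnc_flag", "lnc_far"),
    chrom = "chr1", strand = "+",
    gene_start = c(10000L, 50000L, 90000L),
    gene_end = c(12000L, 52000L, 92000L),
    tss = c(10000L, 50000L, 90000L)
  )
}

test_that("elncRNA calls combine enhancer overlap and CAGE flags", {
  genes <- elnc_genes_fixture()
  enhancers <- tibble::tibble(
    chrom = "chr1",
    start = c(9900L, 90501L),          # spans lnc_over TSS; 501 bp past lnc_far
    end = c(10100L, 90700L),
    name = c("GH_1", "GH_2")
  )
  cage <- tibble::tibble(
    gene_id = genes$gene_id,
    cage_matched = c(TRUE, TRUE, FALSE),
    best_peak = c("p1", "p2_elncRNA", NA),
    summit_distance = c(0L, 3L, NA),
    elncrna_flag = c(FALSE, TRUE, NA)
  )
  out <- call_elncrnas(genes, enhancers, cage, five_prime_window_bp = 500L)
  expect_equal(out$elncrna, c(TRUE, TRUE, FALSE))
  expect_equal(out$source[1:2], c("enhancer_overlap", "cage_flag"))
  expect_equal(out$enhancer_sites[[1]], "GH_1")
  # the enhancer 501 bp beyond the 5' window does not qualify lnc_far
  expect_length(out$enhancer_sites[[3]], 0)
})

test_that("target pairing enforces distance, DE status and concordance", {
  elnc <- tibble::tibble(
    gene_id = "el1", chrom = "chr1", tss = 1000000L, direction = "up"
  )
  pcgs <- tibble::tibble(
    gene_id = c("near_up", "far_up", "near_down", "not_de", "edge"),
    chrom = "chr1",
    tss = c(1200000L, 1250001L + 1000000L, 1010000L, 1100000L, 1250000L),
    de = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    direction = c("up", "up", "down", "none", "up")
  )
  pairs <- find_candidate_targets(elnc, pcgs)
  expect_setequal(pairs$pcg_gene, c("near_up", "edge"))
  expect_equal(pairs$distance_bp[pairs$pcg_gene == "near_up"], 200000L)
  expect_equal(unique(pairs$concordance), "co_induced")
  # the 250 kbp boundary is inclusive; one bp further is out
  pcgs_out <- pcgs
  pcgs_out$tss[pcgs_out$gene_id == "edge"] <- 1250001L
  expect_false("edge" %in% find_candidate_targets(elnc, pcgs_out)$pcg_gene)
  # enlarging the window never removes a pair
  wider <- find_candidate_targets(elnc, pcgs, max_distance_bp = 500000L)
  expect_true(all(paste(pairs$elncrna_gene, pairs$pcg_gene) %in%
                    paste(wider$elncrna_gene, wider$pcg_gene)))
})

test_that("pairs equal a brute-force double loop on a synthetic study", {
  study <- simulate_vsmc_study(mini_cfg(37))
  tr <- study$truth
  pos <- tr$gene_pos
  dir_of <- ifelse(tr$de_log2fc > 0, "up", "down")
  elnc_ids <- sort(c(tr$elnc_enhancer, tr$elnc_cage))
  elnc <- pos[pos$gene_id %in% elnc_ids, ] %>%
    dplyr::mutate(direction = unname(dir_of[.data$gene_id]))
  pcgs <- pos[pos$gene_id %in% tr$coding_genes, ] %>%
    dplyr::mutate(de = .data$gene_id %in% tr$de_coding,
                  direction = ifelse(.data$de, unname(dir_of[.data$gene_id]),
                                     "none"))
  pairs <- find_candidate_targets(elnc, pcgs)

  brute <- list()
  for (i in seq_len(nrow(elnc))) {
    for (j in seq_len(nrow(pcgs))) {
      if (!pcgs$de[j]) next
      if (elnc$chrom[i] != pcgs$chrom[j]) next
      d <- abs(elnc$tss[i] - pcgs$tss[j])
      if (d > 250000) next
      if (elnc$direction[i] != pcgs$direction[j]) next
      brute[[length(brute) + 1]] <- paste(elnc$gene_id[i], pcgs$gene_id[j])
    }
  }
  expect_setequal(paste(pairs$elncrna_gene, pairs$pcg_gene), unlist(brute))
  # every emitted pair satisfies the concordance predicate
  dir_el <- unname(dir_of[pairs$elncrna_gene])
  dir_pc <- unname(dir_of[pairs$pcg_gene])
  expect_true(all(dir_el == dir_pc))
  expect_equal(pairs$concordance,
               ifelse(dir_el == "up", "co_induced", "co_repressed"))
})

test_that("interaction evidence joins through enhancer sites and eQTL links", {
  pairs <- tibble::tibble(
    elncrna_gene = c("el1", "el1", "el2"),
    pcg_gene = c("pcgA", "pcgB", "pcgC"),
    distance_bp = c(1000L, 2000L, 3000L),
    concordance = "co_induced"
  )
  sites <- tibble::tibble(
    gene_id = c("el1", "el2"),
    enhancer_sites = list("GH_1", character())
  )
  evidence <- tibble::tibble(
    site_id = c("GH_1", "GH_1", "GH_9"),
    pcg_id = c("pcgA", "pcgA", "pcgC"),
    evidence_type = c("capture_hic", "erna_coexpression", "capture_hic")
  )
  eqtl <- tibble::tibble(lncrna_gene = "el2", pcg_gene = "pcgC")
  out <- join_interaction_evidence(pairs, sites, evidence, eqtl)
  expect_setequal(out$pairs$evidence[[1]], c("capture_hic", "erna_coexpression"))
  expect_length(out$pairs$evidence[[2]], 0)
  expect_equal(out$pairs$evidence[[3]], "eqtl")  # GH_9 is not el2's site
  expect_equal(nrow(out$evidenced), 2L)

  expect_error(
    join_interaction_evidence(pairs, sites,
                              tibble::tibble(site_id = "GH_1", pcg_id = "pcgA",
                                             evidence_type = "hearsay")),
    "unknown evidence type"
  )
  expect_warning(
    join_interaction_evidence(pairs, sites, evidence,
                              known_genes = "pcgA"),
    "unknown gene"
  )
})

test_that("the planted evidenced-pair count is recovered exactly", {
  cfg <- mini_cfg(43)
  study <- simulate_vsmc_study(cfg)
  tr <- study$truth
  pos <- tr$gene_pos
  dir_of <- ifelse(tr$de_log2fc > 0, "up", "down")
  genes <- pos[pos$gene_id %in% c(tr$elnc_enhancer, tr$elnc_cage), ]
  elnc_tbl <- call_elncrnas(genes, study$enhancers, NULL)
  elnc <- genes %>% dplyr::mutate(direction = unname(dir_of[.data$gene_id]))
  pcgs <- pos[pos$gene_id %in% tr$coding_genes, ] %>%
    dplyr::mutate(de = .data$gene_id %in% tr$de_coding,
                  direction = ifelse(.data$de, unname(dir_of[.data$gene_id]),
                                     "none"))
  pairs <- find_candidate_targets(elnc, pcgs)
  out <- join_interaction_evidence(pairs, elnc_tbl[c("gene_id", "enhancer_sites")],
                                   study$enhancer_evidence)
  expect_equal(nrow(out$evidenced), cfg$n_evidenced_pairs)
  expect_setequal(paste(out$evidenced$elncrna_gene, out$evidenced$pcg_gene),
                  paste(tr$evidenced_pairs$elncrna_gene,
                        tr$evidenced_pairs$pcg_gene))
})
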