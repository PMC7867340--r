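test_that("intron chains list one junction per intron, none for monoexonic", {
  chain <- extract_intron_chain(ex("t1", "g1", "+", c(0, 200), c(100, 300)))
  expect_equal(chain$donor_end, 100L)
  expect_equal(chain$acceptor_start, 200L)

  expect_equal(nrow(extract_intron_chain(ex("t1", "g1", "+", 0, 500))), 0L)

  four <- extract_intron_chain(
    ex("t1", "g1", "-", c(0, 200, 400, 600), c(100, 300, 500, 700)))
  expect_equal(nrow(four), 3L)
  expect_true(all(diff(four$donor_end) > 0))
  expect_error(
    extract_intron_chain(ex("t1", "g1", "+", c(0, 50), c(100, 300))),
    "overlapping"
  )
})

test_that("structure matching classifies identity, shared junctions and strand", {
  reference <- dplyr::bind_rows(
    ex("r1", "g1", "+", c(1000, 2000, 3000), c(1200, 2300, 3400)),
    ex("r2", "g2", "-", c(9000, 10000), c(9300, 10200))
  )
  queries <- dplyr::bind_rows(
    ex("q_copy", "qg1", "+", c(900, 2000, 3000), c(1200, 2300, 3500)),
    ex("q_share", "qg2", "+", c(1100, 2000), c(1200, 2300)),
    ex("q_strand", "qg3", "-", c(1000, 2000, 3000), c(1200, 2300, 3400)),
    ex("q_none", "qg4", "+", c(50000, 60000), c(50500, 60500))
  )
  m <- match_structures(queries, reference)
  got <- stats::setNames(m$match_class, m$query_id)
  expect_equal(got[["q_copy"]], "full_chain")     # same chain, termini differ
  expect_equal(got[["q_share"]], "partial_junction")
  expect_equal(got[["q_strand"]], "no_match")     # antisense chain
  expect_equal(got[["q_none"]], "no_match")
  expect_equal(m$best_reference_id[m$query_id == "q_copy"], "r1")
})

test_that("monoexonic queries follow the reciprocal-overlap rules", {
  reference <- dplyr::bind_rows(
    ex("r_mono", "g1", "+", 1000, 2000),
    ex("r_multi", "g2", "+", c(5000, 6000), c(5500, 6500))
  )
  queries <- dplyr::bind_rows(
    ex("q_recip", "q1", "+", 1100, 2000),   # 90% reciprocal overlap
    ex("q_part", "q2", "+", 1900, 3000),    # some overlap, not reciprocal
    ex("q_multi_ov", "q3", "+", 5400, 6400),# overlaps exons of a multi-exon tx
    ex("q_far", "q4", "+", 30000, 31000)
  )
  m <- match_structures(queries, reference)
  got <- stats::setNames(m$match_class, m$query_id)
  expect_equal(got[["q_recip"]], "full_chain")
  expect_equal(got[["q_part"]], "partial_junction")
  expect_equal(got[["q_multi_ov"]], "partial_junction")
  expect_equal(got[["q_far"]], "no_match")
})

test_that("matching agrees with the brute-force comparator on synthetic annotations", {
  for (seed in c(2, 13)) {
    ann <- simulate_annotation(mini_cfg(seed))
    m <- match_structures(ann$assembled, ann$reference)
    bf <- brute_force_matches(ann$assembled, ann$reference)
    merged <- merge(as.data.frame(m), bf, by = "query_id",
                    suffixes = c("_pkg", "_bf"))
    expect_equal(nrow(merged), length(unique(ann$assembled$transcript_id)))
    expect_equal(merged$match_class_pkg, merged$match_class_bf)
    # and the planted classes are recovered exactly
    truth <- ann$truth$structure_classes
    expect_equal(
      m$match_class[match(truth$transcript_id, m$query_id)],
      truth$class
    )
  }
})

test_that("full-chain matching is symmetric on random transcript pairs", {
  set.seed(41)
  ann <- simulate_annotation(mini_cfg(17))
  tx_ids <- sample(unique(ann$assembled$transcript_id), 12)
  for (id in tx_ids) {
    q <- ann$assembled[ann$assembled$transcript_id == id, ]
    m_fwd <- match_structures(q, ann$reference)
    if (m_fwd$match_class == "full_chain") {
      ref_id <- m_fwd$best_reference_id
      r <- ann$reference[ann$reference$transcript_id == ref_id, ]
      m_rev <- match_structures(r, q)
      expect_equal(m_rev$match_class, "full_chain", info = id)
    }
  }
})

test_that("match-class proportions sum to one per origin", {
  matches <- tibble::tibble(
    query_id = paste0("q", 1:10),
    match_class = c(rep("full_chain", 4), rep("partial_junction", 4),
                    rep("no_match", 2)),
    best_reference_id = NA_character_
  )
  origin <- stats::setNames(rep(c("reference", "assembled"), each = 5),
                            paste0("q", 1:10))
  s <- summarize_match_classes(matches, origin)
  sums <- tapply(s$proportion, s$origin, sum)
  expect_equal(as.vector(sums), c(1, 1))

  origin2 <- c(origin, q_extra = "plaque")
  expect_warning(summarize_match_classes(matches, origin2), "plaque")
})

test_that("CAGE matching is strand-aware and respects the summit window", {
  genes <- tibble::tibble(
    gene_id = c("g_plus", "g_minus", "g_out"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss = c(1000L, 5000L, 9000L)
  )
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(990L, 4995L, 9041L),
    end = c(1010L, 5015L, 9061L),
    strand = c("+", "-", "+"),
    peak_id = c("p0", "p1", "p51"),
    summit = c(1000L, 5005L, 9051L),
    elncrna_flag = FALSE
  )
  m <- match_cage(genes, peaks, window_bp = 50L)
  expect_equal(m$cage_matched, c(TRUE, TRUE, FALSE))
  expect_equal(m$summit_distance[1], 0L)
  # minus strand: summit downstream of TSS (smaller coordinate side)
  expect_equal(m$summit_distance[2], 5L)

  # widening the window never loses a match
  m_wide <- match_cage(genes, peaks, window_bp = 60L)
  expect_true(all(m$cage_matched <= m_wide$cage_matched))
  expect_true(m_wide$cage_matched[3])
})

test_that("planted CAGE-matched fractions are recovered exactly", {
  cfg <- mini_cfg(23)
  study <- simulate_vsmc_study(cfg)
  lnc <- study$truth$gene_plan
  lnc <- lnc$final_gene[lnc$type %in% c("lncrna", "novel")]
  genes <- gene_summary(
    dplyr::bind_rows(study$reference, study$assembled) %>%
      dplyr::mutate(gene_id = ifelse(
        grepl("^ASMG\\.nov", .data$gene_id),
        study$truth$novel_genes$final_gene[
          match(.data$gene_id, study$truth$novel_genes$gene_id)],
        .data$gene_id))
  )
  genes <- genes[genes$gene_id %in% lnc, ]
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", study$cage$chrom,
                     study$cage$start, study$cage$end, study$cage$name,
                     study$cage$score, study$cage$strand), f)
  m <- match_cage(genes, read_cage_bed(f))
  expect_setequal(m$gene_id[m$cage_matched], study$truth$cage_matched)
})

test_that("five-prime incompleteness follows gap / (gap + first exon)", {
  expect_equal(five_prime_completeness(0, 200), 0)
  expect_equal(five_prime_completeness(20, 180), 0.10)
  # summit downstream of the start clamps to complete
  expect_equal(five_prime_completeness(-10, 200), 0)
  expect_true(all(five_prime_completeness(c(0, 5, 500), 100) < 1))
})
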