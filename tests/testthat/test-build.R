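make_ref_fixture <- function() {
  dplyr::bind_rows(
    ex("sp_low", "gA", "+", c(0, 1000), c(300, 1400)),        # spliced, low FPKM
    ex("sp_299", "gB", "+", c(5000, 6000), c(5150, 6149)),    # 299 bp
    ex("sp_300", "gC", "+", c(10000, 11000), c(10150, 11150)),# 300 bp boundary
    ex("mono_low", "gD", "+", 20000, 20500),                  # unspliced
    ex("mono_ok", "gE", "+", 30000, 30500),
    ex("sp_ok", "gF", "+", c(40000, 41000), c(40200, 41300))
  )
}

test_that("reference filter applies the length and FPKM rules at boundaries", {
  exons <- make_ref_fixture()
  fpkm <- c(sp_low = 0.4, sp_299 = 0.6, sp_300 = 0.6, mono_low = 0.9,
            mono_ok = 1.0, sp_ok = 0.6)
  kept <- unique(filter_reference(exons, fpkm)$transcript_id)
  expect_setequal(kept, c("sp_300", "mono_ok", "sp_ok"))

  # spliced boundary: 0.49 removed, 0.50 retained
  fpkm2 <- c(sp_ok = 0.49, sp_300 = 0.50, sp_low = 2, sp_299 = 2,
             mono_low = 2, mono_ok = 2)
  kept2 <- unique(filter_reference(exons, fpkm2)$transcript_id)
  expect_false("sp_ok" %in% kept2)
  expect_true("sp_300" %in% kept2)
  expect_false("sp_299" %in% kept2)  # still short

  # transcripts with no expression value count as 0 and drop out
  kept3 <- unique(filter_reference(exons, c(sp_ok = 1))$transcript_id)
  expect_equal(kept3, "sp_ok")
})

test_that("raising any filter threshold never enlarges the retained set", {
  set.seed(21)
  ann <- simulate_annotation(mini_cfg(3))
  tx <- unique(ann$reference$transcript_id)
  fpkm <- stats::setNames(stats::runif(length(tx), 0, 3), tx)
  base <- unique(filter_reference(ann$reference, fpkm)$transcript_id)
  for (cfg in list(build_config(min_transcript_length = 400),
                   build_config(min_fpkm_spliced = 1.0),
                   build_config(min_fpkm_unspliced = 2.0))) {
    stricter <- unique(filter_reference(ann$reference, fpkm, cfg)$transcript_id)
    expect_true(all(stricter %in% base))
  }
})

test_that("merging drops chain-identical assembled transcripts and attaches isoforms", {
  reference <- dplyr::bind_rows(
    ex("ref1", "gREF", "+", c(1000, 2000, 3000), c(1200, 2300, 3400))
  )
  assembled <- dplyr::bind_rows(
    # same intron chain, longer terminal exons: redundant
    ex("asm_dup", "ga1", "+", c(900, 2000, 3000), c(1200, 2300, 3600)),
    # overlaps gREF exon 1 on the same strand: novel isoform of gREF
    ex("asm_iso", "ga2", "+", c(1100, 5000), c(1300, 5400)),
    # antisense overlap: distinct (novel) gene
    ex("asm_anti", "ga3", "-", c(1000, 2000), c(1200, 2300)),
    # intergenic: novel gene
    ex("asm_new", "ga4", "+", c(50000, 51000), c(50400, 51400))
  )
  et <- merge_transcriptomes(assembled, reference)
  tx <- transcript_summary(et$exons)
  expect_false("asm_dup" %in% tx$transcript_id)
  expect_equal(tx$gene_id[tx$transcript_id == "asm_iso"], "gREF")
  # novel serials in genome order: antisense locus precedes the intergenic one
  expect_equal(tx$gene_id[tx$transcript_id == "asm_anti"], "MSTRG.1")
  expect_equal(tx$gene_id[tx$transcript_id == "asm_new"], "MSTRG.2")
  expect_error(merge_transcriptomes(reference, reference), "collision")
})

test_that("planted novel intergenic genes all gain the MSTRG prefix, exactly", {
  cfg <- mini_cfg(11)
  ann <- simulate_annotation(cfg)
  tx <- unique(ann$reference$transcript_id)
  fpkm <- stats::setNames(rep(5, length(tx)), tx)
  merged <- merge_transcriptomes(ann$assembled,
                                 filter_reference(ann$reference, fpkm))
  genes <- unique(merged$exons$gene_id)
  mstrg <- grep("^MSTRG\\.", genes, value = TRUE)
  expect_equal(length(mstrg), cfg$n_novel_genes)
  expect_setequal(mstrg, ann$truth$novel_genes$final_gene)
})

test_that("non-redundant union merges chains, unions 5' ends, maps membership", {
  a <- merge_transcriptomes(
    ex("asmA", "gA", "+", c(50000, 51000), c(50400, 51400)),
    ex("r1", "g1", "+", c(1000, 2000), c(1230, 2400)),
    dataset_tag = "svSMC"
  )
  # same chain as r1 but 5' start 30 bp upstream; plus a disjoint gene
  b <- merge_transcriptomes(
    ex("asmB", "gB", "-", c(80000, 81000), c(80500, 81300)),
    ex("r1b", "g1b", "+", c(970, 2000), c(1230, 2400)),
    dataset_tag = "aoSMC"
  )
  un <- build_union(list(a, b))
  sm <- transcript_summary(un$exons)
  shared <- sm[sm$chrom == "chr1" & sm$strand == "+" & sm$tx_start < 5000, ]
  expect_equal(nrow(shared), 1L)         # one merged record for the chain
  expect_equal(shared$tx_start, 970L)    # 5' = min start across sources
  expect_equal(nrow(un$membership), 3L)  # merged gene + 2 source-unique genes
  both <- un$membership$sources[[match(shared$gene_id, un$membership$gene_id)]]
  expect_setequal(both, c("svSMC", "aoSMC"))
})

test_that("union of a transcriptome with itself preserves the gene count", {
  ann <- simulate_annotation(mini_cfg(5))
  tx <- unique(ann$reference$transcript_id)
  fpkm <- stats::setNames(rep(5, length(tx)), tx)
  et <- merge_transcriptomes(ann$assembled,
                             filter_reference(ann$reference, fpkm),
                             dataset_tag = "d1")
  et2 <- et; et2$dataset_tag <- "d2"
  un <- build_union(list(et, et2))
  expect_equal(nrow(un$membership), length(unique(et$exons$gene_id)))
})

test_that("union rejects mixed chromosome naming and adds disjoint sets", {
  a <- merge_transcriptomes(
    ex("a1", "gA", "+", c(50000, 51000), c(50400, 51400)),
    ex("r1", "g1", "+", c(1000, 2000), c(1230, 2400)),
    dataset_tag = "d1"
  )
  b_plain <- merge_transcriptomes(
    ex("b1", "gB", "+", c(50000, 51000), c(50400, 51400), chrom = "2"),
    ex("r2", "g2", "+", c(1000, 2000), c(1230, 2400), chrom = "2"),
    dataset_tag = "d2"
  )
  expect_error(build_union(list(a, b_plain)), "naming mismatch")

  b <- merge_transcriptomes(
    ex("b1", "gB", "+", c(150000, 151000), c(150400, 151400), chrom = "chr9"),
    ex("r2", "g2", "+", c(101000, 102000), c(101230, 102400), chrom = "chr9"),
    dataset_tag = "d2"
  )
  un <- build_union(list(a, b))
  expect_equal(nrow(un$membership),
               length(unique(a$exons$gene_id)) + length(unique(b$exons$gene_id)))
})

test_that("single-exon union redundancy follows the reciprocal-overlap rule", {
  a <- merge_transcriptomes(
    ex("a1", "gA", "+", 50000, 51000),
    ex("r1", "g1", "+", c(1000, 2000), c(1230, 2400)),
    dataset_tag = "d1"
  )
  # 60% reciprocal overlap with a1: merged at the 0.5 default
  b <- merge_transcriptomes(
    ex("b1", "gB", "+", 50400, 51400),
    ex("r1b", "g1b", "+", c(1000, 2000), c(1230, 2400)),
    dataset_tag = "d2"
  )
  un_default <- build_union(list(a, b))
  un_strict <- build_union(list(a, b), mono_reciprocal_overlap = 0.9)
  n_mono <- function(u) sum(transcript_summary(u$exons)$n_exons == 1)
  expect_equal(n_mono(un_default), 1L)
  expect_equal(n_mono(un_strict), 2L)
})
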