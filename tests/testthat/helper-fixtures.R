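# Shared fixture builders: everything is generated in code at test time.

# Compact exon-table builder: ex("tx1", "g1", "+", c(0, 100), c(50, 200))
ex <- function(transcript_id, gene_id, strand, starts, ends, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = strand, transcript_id = transcript_id, gene_id = gene_id
  )
}

# A small study configuration for fast end-to-end tests (toy genome shrunk,
# all planted-entity counts reduced proportionally).
mini_cfg <- function(seed = 101) {
  sim_config(
    seed = seed,
    n_ref_coding = 80, n_ref_lncrna = 50, n_ref_putative = 5,
    n_novel_genes = 12, n_full_copies = 12, n_novel_isoforms = 12,
    n_extra_artefacts = 4,
    enriched_folds = c(4, 4, 5, 6, 20, 41),
    n_elnc_enhancer = 6, n_elnc_cage = 3, n_evidenced_pairs = 2,
    chrom_sizes = c(chr1 = 2e6, chr2 = 2e6)
  )
}

# Write a study to disk and return the path list run_pipeline() expects.
study_paths <- function(dir) {
  files <- c(
    reference_gtf = "ref.gtf", assembled_gtf = "asm.gtf",
    expression_tsv = "expr.tsv", gene_expression_tsv = "gene_expr.tsv",
    samples_tsv = "samples.tsv", de_tsv = "de.tsv",
    coding_calls_tsv = "coding_calls.tsv", cage_bed = "cage.bed",
    atlas_tsv = "atlas.tsv", enhancers_bed = "enhancers.bed",
    evidence_tsv = "evidence.tsv", eqtl_tsv = "eqtl.tsv",
    second_expression_tsv = "second_expr.tsv",
    second_samples_tsv = "second_samples.tsv"
  )
  out <- as.list(file.path(dir, files))
  names(out) <- names(files)
  out
}

# Brute-force O(n^2) structure-match comparator, independent of the package's
# keyed implementation: compares junction lists pairwise.
brute_force_matches <- function(queries, reference, mono_reciprocal_overlap = 0.8) {
  tx_list <- function(exons) {
    split(exons[order(exons$start), ], exons$transcript_id[order(exons$start)])
  }
  junctions <- function(e) {
    e <- e[order(e$start), ]
    if (nrow(e) < 2) return(NULL)
    paste(head(e$end, -1), tail(e$start, -1), sep = "-")
  }
  q <- tx_list(queries); r <- tx_list(reference)
  r_j <- lapply(r, junctions)
  out <- lapply(names(q), function(qid) {
    qe <- q[[qid]]
    qj <- junctions(qe)
    cls <- "no_match"
    for (rid in names(r)) {
      re <- r[[rid]]
      if (re$chrom[1] != qe$chrom[1] || re$strand[1] != qe$strand[1]) next
      rj <- r_j[[rid]]
      if (!is.null(qj)) {
        if (!is.null(rj) && length(qj) == length(rj) && all(qj == rj)) {
          cls <- "full_chain"; break
        }
        if (!is.null(rj) && any(qj %in% rj)) cls <- "partial_junction"
      } else {
        # monoexonic query: overlap rules against every reference transcript
        q_iv <- c(qe$start[1], qe$end[1])
        ov_any <- any(pmin(re$end, q_iv[2]) - pmax(re$start, q_iv[1]) > 0)
        if (ov_any && cls == "no_match") cls <- "partial_junction"
        if (is.null(rj)) {
          ov <- min(re$end[1], q_iv[2]) - max(re$start[1], q_iv[1])
          q_len <- q_iv[2] - q_iv[1]
          r_len <- re$end[1] - re$start[1]
          if (ov >= mono_reciprocal_overlap * q_len &&
              ov >= mono_reciprocal_overlap * r_len) {
            cls <- "full_chain"; break
          }
        }
      }
    }
    data.frame(query_id = qid, match_class = cls)
  })
  do.call(rbind, out)
}

# Full hypergeometric enumeration of the two-sided Fisher p-value using
# binomial-coefficient ratios (independent of dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  m <- a + b
  k <- a + c
  lo <- max(0, k - (n - m)); hi <- min(k, m)
  dens <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n - m, k - x) / choose(n, k)
  }, numeric(1))
  p_obs <- dens[a - lo + 1]
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}
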