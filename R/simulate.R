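#' Configuration of the synthetic VSMC transcriptome study
#'
#' The generator emulates the shape of the real study inputs on a toy genome
#' (two chromosomes of 10 Mbp, coordinates only): a reference annotation with
#' coding, lncRNA and putative-lncRNA genes; an assembled transcript set
#' containing exact reference copies (full intron-chain matches), novel
#' isoforms sharing splice junctions, and novel intergenic genes; reference
#' artefacts violating the assembly filters; per-sample FPKM tables with
#' planted differential expression; CAGE peaks jittered around true TSSs; a
#' cell-category expression atlas with enrichment folds realised exactly by
#' construction; and enhancer sites over planted elncRNA 5' ends with
#' interaction-evidence rows for planted target pairs. Every planted entity is
#' recorded in a truth object so each pipeline stage can be checked for exact
#' recovery.
#'
#' @param seed Master seed; each emitted component uses its own stream derived
#'   from it, so adding one output never shifts another's draws.
#' @param n_ref_coding,n_ref_lncrna,n_ref_putative Reference gene counts.
#' @param n_novel_genes Novel intergenic (assembled-only) lncRNA genes.
#' @param n_full_copies Assembled exact copies of reference lncRNA transcripts.
#' @param n_novel_isoforms Assembled junction-sharing novel isoforms.
#' @param n_extra_artefacts Random reference artefacts beyond the six fixed
#'   boundary-case transcripts.
#' @param conditions,samples_per_condition Experimental design.
#' @param fpkm_meanlog,fpkm_sdlog Lognormal parameters of per-gene baseline
#'   FPKM; `sample_sdlog` is the per-sample multiplicative noise.
#' @param sample_sdlog Per-sample lognormal noise sd (log scale).
#' @param de_fraction Fraction of lncRNA (and of coding) genes planted as
#'   differentially expressed.
#' @param fc_magnitudes Planted |log2fc| values for DE genes.
#' @param null_log2fc_max Null genes draw log2fc uniformly within +/- this
#'   (kept below the 1.5-fold threshold so the planted DE set is exact).
#' @param cage_fraction_reference,cage_fraction_assembled Fractions of lncRNA
#'   genes per origin given a CAGE peak within the matching window.
#' @param cage_jitter_sd CAGE summit jitter sd in bp (truncated at
#'   `cage_jitter_max` so planted peaks stay within the default +/-50 bp
#'   window).
#' @param cage_jitter_max Truncation bound for the jitter.
#' @param enriched_folds Planted atlas enrichment folds (values below 5 are
#'   deliberate sub-threshold plants).
#' @param atlas_baseline,atlas_pseudocount Constant off-category expression
#'   and the pseudocount used when realising folds exactly.
#' @param n_elnc_enhancer,n_elnc_cage Planted elncRNAs via enhancer overlap
#'   and via flagged CAGE peaks.
#' @param n_evidenced_pairs Planted target pairs given interaction evidence.
#' @param max_target_distance Target-pairing window in bp.
#' @param second_detect_fraction Fraction of novel genes detectable in the
#'   second (tissue) expression dataset.
#' @param chrom_sizes Named vector of toy-chromosome lengths in bp.
#' @param slot_spacing Width of the per-gene genome slots in bp.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ref_coding = 700L,
                       n_ref_lncrna = 180L,
                       n_ref_putative = 20L,
                       n_novel_genes = 60L,
                       n_full_copies = 80L,
                       n_novel_isoforms = 80L,
                       n_extra_artefacts = 24L,
                       conditions = c("quiescent", "stimulated"),
                       samples_per_condition = 5L,
                       fpkm_meanlog = 1.5,
                       fpkm_sdlog = 0.8,
                       sample_sdlog = 0.25,
                       de_fraction = 0.27,
                       fc_magnitudes = c(1, 1.5, 2, 3),
                       null_log2fc_max = 0.4,
                       cage_fraction_reference = 0.869,
                       cage_fraction_assembled = 0.743,
                       cage_jitter_sd = 10,
                       cage_jitter_max = 40,
                       enriched_folds = rep(c(4, 5, 6, 20, 41),
                                            times = c(6, 5, 5, 4, 2)),
                       atlas_baseline = 2,
                       atlas_pseudocount = 0.1,
                       n_elnc_enhancer = 30L,
                       n_elnc_cage = 15L,
                       n_evidenced_pairs = 13L,
                       max_target_distance = 250000L,
                       second_detect_fraction = 0.24,
                       chrom_sizes = c(chr1 = 10e6, chr2 = 10e6),
                       slot_spacing = 20000L) {
  cfg <- list(
    seed = as.integer(seed),
    n_ref_coding = n_ref_coding, n_ref_lncrna = n_ref_lncrna,
    n_ref_putative = n_ref_putative, n_novel_genes = n_novel_genes,
    n_full_copies = n_full_copies, n_novel_isoforms = n_novel_isoforms,
    n_extra_artefacts = n_extra_artefacts,
    conditions = conditions, samples_per_condition = samples_per_condition,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    sample_sdlog = sample_sdlog,
    de_fraction = de_fraction, fc_magnitudes = fc_magnitudes,
    null_log2fc_max = null_log2fc_max,
    cage_fraction_reference = cage_fraction_reference,
    cage_fraction_assembled = cage_fraction_assembled,
    cage_jitter_sd = cage_jitter_sd, cage_jitter_max = cage_jitter_max,
    enriched_folds = enriched_folds,
    atlas_baseline = atlas_baseline, atlas_pseudocount = atlas_pseudocount,
    n_elnc_enhancer = n_elnc_enhancer, n_elnc_cage = n_elnc_cage,
    n_evidenced_pairs = n_evidenced_pairs,
    max_target_distance = max_target_distance,
    second_detect_fraction = second_detect_fraction,
    chrom_sizes = chrom_sizes,
    slot_spacing = as.integer(slot_spacing),
    vsmc_categories = c("VSMC_saphenous", "VSMC_aortic", "VSMC_coronary"),
    other_categories = c(
      "fibroblast_dermal", "fibroblast_cardiac", "endothelial_aortic",
      "endothelial_vein", "epithelial_renal", "epithelial_bronchial",
      "monocyte", "t_cell", "b_cell", "nk_cell", "hepatocyte",
      "keratinocyte", "osteoblast", "chondrocyte", "adipocyte",
      "neuron_cortical", "astrocyte"
    )
  )
  stopifnot(cfg$n_ref_lncrna >= 1, cfg$n_novel_genes >= 1,
            cfg$samples_per_condition >= 1, length(cfg$conditions) >= 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1)
  structure(cfg, class = "sim_config")
}

## Internal: one multi/mono-exon structure starting at `start0`.
make_exon_chain <- function(start0, n_exons) {
  if (n_exons == 1) {
    lens <- sample(400:800, 1)
    introns <- integer()
  } else {
    lens <- sample(150:400, n_exons, replace = TRUE)
    introns <- sample(500:2500, n_exons - 1, replace = TRUE)
  }
  starts <- start0 + cumsum(c(0L, utils::head(lens, -1) + introns))
  tibble(start = as.integer(starts), end = as.integer(starts + lens))
}

## Internal: drop exon `k` from a chain (exon skipping).
skip_exon <- function(chain, k) chain[-k, , drop = FALSE]

#' Generate the synthetic reference and assembled annotations
#'
#' @param cfg A [sim_config()].
#' @return List: `reference` and `assembled` exon tables, `coding_calls`
#'   tibble (`transcript_id`, `gene_id`, `call`), and `truth` (gene plan,
#'   planted structure classes, expected novel-gene ids, artefact fate).
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_boundary <- 6L
  n_art <- n_boundary + cfg$n_extra_artefacts
  n_genes <- cfg$n_ref_coding + cfg$n_ref_lncrna + cfg$n_ref_putative +
    cfg$n_novel_genes + n_art
  slots_per_chrom <- as.integer(cfg$chrom_sizes %/% cfg$slot_spacing)
  n_slots <- sum(slots_per_chrom)
  if (n_genes > n_slots) {
    stop("infeasible plan: ", n_genes, " genes exceed ", n_slots,
         " toy-genome slots")
  }

  plan <- tibble(
    gene_id = c(
      sprintf("PCG.%04d", seq_len(cfg$n_ref_coding)),
      sprintf("LNC.%04d", seq_len(cfg$n_ref_lncrna)),
      sprintf("PUT.%04d", seq_len(cfg$n_ref_putative)),
      sprintf("ASMG.nov.%03d", seq_len(cfg$n_novel_genes)),
      sprintf("ART.%03d", seq_len(n_art))
    ),
    type = c(
      rep("coding", cfg$n_ref_coding),
      rep("lncrna", cfg$n_ref_lncrna),
      rep("putative", cfg$n_ref_putative),
      rep("novel", cfg$n_novel_genes),
      rep("artefact", n_art)
    )
  )
  slot <- sample.int(n_slots, n_genes)
  plan$chrom <- ifelse(slot <= slots_per_chrom[1], names(cfg$chrom_sizes)[1],
                       names(cfg$chrom_sizes)[2])
  slot_in_chrom <- ifelse(slot <= slots_per_chrom[1], slot,
                          slot - slots_per_chrom[1])
  plan$slot_start <- as.integer((slot_in_chrom - 1L) * cfg$slot_spacing +
                                  500L + sample(0:1000, n_genes, replace = TRUE))
  plan$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  plan$n_exons <- sample(2:6, n_genes, replace = TRUE)
  # ~10% of lncRNA-like genes monoexonic
  mono_ok <- plan$type %in% c("lncrna", "novel")
  plan$n_exons[mono_ok & stats::runif(n_genes) < 0.10] <- 1L

  # artefact plan: six fixed boundary cases, then random violations
  art_idx <- which(plan$type == "artefact")
  art_kind <- c("short299", "len300_ok", "spliced049", "spliced050",
                "mono090", "mono100",
                sample(c("short", "spliced_low", "mono_low"),
                       cfg$n_extra_artefacts, replace = TRUE))
  plan$art_kind <- NA_character_
  plan$art_kind[art_idx] <- art_kind
  plan$n_exons[art_idx] <- ifelse(grepl("mono", art_kind), 1L, 2L)

  exon_rows <- vector("list", n_genes)
  iso_counter <- 0L
  ref_variant_of <- character()
  for (i in seq_len(n_genes)) {
    g <- plan$gene_id[i]
    kind <- plan$art_kind[i]
    if (!is.na(kind)) {
      chain <- switch(
        sub("[0-9]+$", "", sub("_.*$", "", kind)),
        short299 = ,
        short = {
          lens <- if (kind == "short299") c(150L, 149L) else
            c(sample(100:140, 1), sample(100:140, 1))
          tibble(start = plan$slot_start[i] + c(0L, lens[1] + 800L),
                 end = plan$slot_start[i] + c(lens[1], lens[1] + 800L + lens[2]))
        },
        len = tibble(start = plan$slot_start[i] + c(0L, 950L),
                     end = plan$slot_start[i] + c(150L, 1100L)),
        spliced = make_exon_chain(plan$slot_start[i], 2L),
        mono = tibble(start = plan$slot_start[i],
                      end = plan$slot_start[i] + 500L)
      )
      exon_rows[[i]] <- chain %>%
        mutate(chrom = plan$chrom[i], strand = plan$strand[i],
               transcript_id = paste0(g, ".t1"), gene_id = g)
      next
    }
    chain <- make_exon_chain(plan$slot_start[i], plan$n_exons[i])
    iso <- list(chain)
    # a reference variant isoform (skip exon 2) for some multi-exon genes
    if (plan$type[i] %in% c("coding", "lncrna", "putative", "novel") &&
        plan$n_exons[i] >= 4 && stats::runif(1) < 0.35) {
      iso <- c(iso, list(skip_exon(chain, 2L)))
      ref_variant_of <- c(ref_variant_of, g)
    }
    exon_rows[[i]] <- bind_rows(lapply(seq_along(iso), function(j) {
      iso[[j]] %>%
        mutate(chrom = plan$chrom[i], strand = plan$strand[i],
               transcript_id = paste0(g, ".t", j), gene_id = g)
    }))
  }
  all_exons <- bind_rows(exon_rows) %>%
    select("chrom", "start", "end", "strand", "transcript_id", "gene_id")

  is_ref_gene <- plan$type %in% c("coding", "lncrna", "putative", "artefact")
  reference <- all_exons %>%
    filter(.data$gene_id %in% plan$gene_id[is_ref_gene])
  novel_exons <- all_exons %>%
    filter(.data$gene_id %in% plan$gene_id[plan$type == "novel"])

  # assembled set: exact copies + junction-sharing novel isoforms + novel genes
  ref_lnc_tx <- transcript_summary(
    reference %>% filter(.data$gene_id %in% plan$gene_id[plan$type == "lncrna"])
  ) %>% filter(.data$n_exons >= 2)
  n_copies <- min(cfg$n_full_copies, nrow(ref_lnc_tx))
  copy_ids <- sort(sample(ref_lnc_tx$transcript_id, n_copies))
  copies <- reference %>%
    filter(.data$transcript_id %in% copy_ids) %>%
    mutate(gene_id = paste0("ASMG.copy.", match(.data$transcript_id, copy_ids)),
           transcript_id = paste0("ASM.copy.",
                                  match(.data$transcript_id, copy_ids), ".t1"))

  iso_parent <- plan %>%
    filter(.data$type == "lncrna", .data$n_exons >= 4)
  n_iso <- min(cfg$n_novel_isoforms, nrow(iso_parent))
  iso_genes <- sort(sample(iso_parent$gene_id, n_iso))
  novel_iso <- bind_rows(lapply(seq_along(iso_genes), function(j) {
    g <- iso_genes[j]
    base <- all_exons %>%
      filter(.data$gene_id == g, .data$transcript_id == paste0(g, ".t1")) %>%
      arrange(.data$start)
    # skip the last internal exon: distinct from the reference variant (exon 2)
    variant <- skip_exon(base, nrow(base) - 1L)
    variant %>%
      mutate(transcript_id = paste0("ASM.iso.", j, ".t1"),
             gene_id = paste0("ASMG.iso.", j))
  }))

  asm_novel <- novel_exons %>%
    mutate(transcript_id = sub("^ASMG", "ASM", .data$transcript_id))
  assembled <- bind_rows(copies, novel_iso, asm_novel) %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)

  # expected novel-gene ids after merging: MSTRG serials in genome order
  novel_order <- plan %>%
    filter(.data$type == "novel") %>%
    arrange(.data$chrom, .data$slot_start, .data$gene_id) %>%
    mutate(final_gene = paste0("MSTRG.", dplyr::row_number()))
  final_gene_of <- stats::setNames(plan$gene_id, plan$gene_id)
  final_gene_of[novel_order$gene_id] <- novel_order$final_gene

  # planted structure classes of assembled transcripts vs the reference
  structure_truth <- bind_rows(
    tibble(transcript_id = unique(copies$transcript_id), class = "full_chain"),
    tibble(transcript_id = unique(novel_iso$transcript_id),
           class = "partial_junction"),
    tibble(transcript_id = unique(asm_novel$transcript_id), class = "no_match")
  )

  artefact_truth <- plan %>%
    filter(.data$type == "artefact") %>%
    mutate(
      transcript_id = paste0(.data$gene_id, ".t1"),
      removed = !.data$art_kind %in% c("len300_ok", "spliced050", "mono100")
    ) %>%
    select("transcript_id", "gene_id", "art_kind", "removed")

  coding_calls <- transcript_summary(bind_rows(reference, assembled)) %>%
    select("transcript_id", "gene_id") %>%
    mutate(call = dplyr::case_when(
      grepl("^PCG\\.|^ART\\.", .data$gene_id) ~ "coding",
      grepl("^ASMG\\.copy\\.", .data$gene_id) ~ "high_confidence_lncRNA",
      grepl("^PUT\\.", .data$gene_id) ~ "putative_lncRNA",
      TRUE ~ "high_confidence_lncRNA"
    ))

  gene_plan <- plan %>%
    mutate(final_gene = unname(final_gene_of[.data$gene_id]))
  gene_pos <- gene_summary(all_exons) %>%
    mutate(gene_id = unname(final_gene_of[.data$gene_id]))

  list(
    reference = reference,
    assembled = assembled,
    coding_calls = coding_calls,
    truth = list(
      gene_plan = gene_plan,
      gene_pos = gene_pos,
      novel_genes = novel_order %>%
        select("gene_id", "final_gene", "chrom", "slot_start", "strand"),
      structure_classes = structure_truth,
      artefacts = artefact_truth,
      iso_genes = iso_genes,
      copy_source = copy_ids
    )
  )
}

#' Generate per-sample expression and the planted DE table
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List: `tx_expr` and `gene_expr` ([expression_matrix()] objects on
#'   merged-annotation ids), `de_table`, `second_expr` (tissue dataset),
#'   `truth` additions (planted DE genes, minor isoforms, detectable novel
#'   genes).
#' @export
simulate_expression <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  plan <- ann$truth$gene_plan
  samples <- paste0(rep(cfg$conditions, each = cfg$samples_per_condition),
                    "_s", seq_len(cfg$samples_per_condition))
  condition_of <- stats::setNames(
    rep(cfg$conditions, each = cfg$samples_per_condition), samples
  )

  lnc_genes <- plan$final_gene[plan$type %in% c("lncrna", "novel")]
  coding_genes <- plan$final_gene[plan$type == "coding"]
  putative_genes <- plan$final_gene[plan$type == "putative"]
  main_genes <- c(coding_genes, lnc_genes, putative_genes)

  # planted DE sets (lncRNA and coding separately, clearly separated effects)
  de_lnc <- sort(sample(lnc_genes, round(cfg$de_fraction * length(lnc_genes))))
  de_coding <- sort(sample(coding_genes,
                           round(cfg$de_fraction * length(coding_genes))))
  de_genes <- c(de_lnc, de_coding)
  de_l2fc <- stats::setNames(
    sample(cfg$fc_magnitudes, length(de_genes), replace = TRUE) *
      sample(c(-1, 1), length(de_genes), replace = TRUE),
    de_genes
  )

  baseline <- stats::setNames(
    stats::rlnorm(length(main_genes), cfg$fpkm_meanlog, cfg$fpkm_sdlog),
    main_genes
  )
  # planted entities must flow through the expressed/robust filters with
  # headroom: lncRNA genes stay clear of the reference-filter FPKM cut even
  # at their minimum isoform share, and DE genes keep that margin after a
  # down-regulation of up to 1/8 halves their across-sample mean
  baseline[lnc_genes] <- pmax(baseline[lnc_genes],
                              stats::runif(length(lnc_genes), 4, 8))
  baseline[de_genes] <- pmax(baseline[de_genes], 8)

  stim <- cfg$conditions[length(cfg$conditions)]
  n_s <- length(samples)
  gene_vals <- t(vapply(main_genes, function(g) {
    fc <- if (g %in% names(de_l2fc)) de_l2fc[[g]] else 0
    mult <- ifelse(condition_of == stim, 2^fc, 1)
    baseline[[g]] * mult *
      stats::rlnorm(n_s, -cfg$sample_sdlog^2 / 2, cfg$sample_sdlog)
  }, numeric(n_s)))
  colnames(gene_vals) <- samples

  # isoform proportions; plant minor isoforms on some assembled lncRNA genes
  merged_gene_of <- stats::setNames(plan$final_gene, plan$gene_id)
  tx <- transcript_summary(bind_rows(ann$reference, ann$assembled)) %>%
    filter(!grepl("^ART\\.|^ASMG\\.copy", .data$gene_id)) %>%
    mutate(final_gene = ifelse(grepl("^ASMG\\.iso\\.", .data$gene_id),
                               NA_character_,
                               unname(merged_gene_of[.data$gene_id])))
  # novel isoforms attach to their parent reference lncRNA gene after merging
  iso_map <- stats::setNames(ann$truth$iso_genes,
                             paste0("ASM.iso.", seq_along(ann$truth$iso_genes), ".t1"))
  tx$final_gene[is.na(tx$final_gene)] <-
    unname(merged_gene_of[iso_map[tx$transcript_id[is.na(tx$final_gene)]]])

  minor_truth <- list()
  tx_rows <- list()
  for (g in unique(tx$final_gene)) {
    members <- tx$transcript_id[tx$final_gene == g]
    k <- length(members)
    if (k == 1) {
      props <- 1
    } else if (g %in% lnc_genes && any(grepl("^ASM\\.", members)) &&
               stats::runif(1) < 0.3) {
      # plant one sub-10% minor isoform on a newly assembled lncRNA gene;
      # the minor member is an assembled transcript so the reference copy of
      # the gene keeps enough expression to survive the reference filter
      minor <- members[grepl("^ASM\\.", members)][1]
      props <- rep((1 - 0.07) / (k - 1), k)
      props[members == minor] <- 0.07
      minor_truth[[g]] <- minor
    } else {
      raw <- stats::runif(k, 0.6, 1)
      props <- raw / sum(raw)
    }
    vals <- if (g %in% rownames(gene_vals)) gene_vals[g, ] else
      stats::rlnorm(n_s, 0, 0.2)  # genes outside the main table
    for (j in seq_len(k)) {
      tx_rows[[members[j]]] <- vals * props[j]
    }
  }
  tx_vals <- do.call(rbind, tx_rows)
  colnames(tx_vals) <- samples

  # artefact transcript expression: planted FPKM bands per kind
  art <- ann$truth$artefacts
  art_fpkm <- vapply(art$art_kind, function(kind) {
    switch(kind,
           short299 = 2, len300_ok = 2, spliced049 = 0.49, spliced050 = 0.5,
           mono090 = 0.9, mono100 = 1.0,
           short = stats::runif(1, 1.5, 4),
           spliced_low = stats::runif(1, 0.05, 0.45),
           mono_low = stats::runif(1, 0.3, 0.9))
  }, numeric(1))
  art_vals <- matrix(rep(art_fpkm, n_s), ncol = n_s,
                     dimnames = list(art$transcript_id, samples))
  tx_vals <- rbind(tx_vals, art_vals)

  de_table <- tibble(gene_id = main_genes) %>%
    mutate(
      log2fc = ifelse(.data$gene_id %in% names(de_l2fc),
                      unname(de_l2fc[.data$gene_id]),
                      stats::runif(length(main_genes),
                                   -cfg$null_log2fc_max, cfg$null_log2fc_max)),
      pvalue = ifelse(.data$gene_id %in% names(de_l2fc),
                      stats::runif(length(main_genes), 1e-6, 0.009),
                      stats::runif(length(main_genes)))
    )

  # second (tissue) dataset: gene-level, planted detectability of novel genes
  novel_final <- ann$truth$novel_genes$final_gene
  n_detect <- round(cfg$second_detect_fraction * length(novel_final))
  detected_novel <- sort(sample(novel_final, n_detect))
  second_vals <- matrix(
    stats::runif(length(main_genes) * 3, 0.0, 0.8), ncol = 3,
    dimnames = list(main_genes, paste0("plaque_s", 1:3))
  )
  second_vals[detected_novel, ] <- stats::runif(n_detect * 3, 2, 6)
  ref_detected <- sample(setdiff(main_genes, novel_final),
                         round(0.5 * (length(main_genes) - length(novel_final))))
  second_vals[ref_detected, ] <- stats::runif(length(ref_detected) * 3, 1.5, 6)
  second_condition <- stats::setNames(rep("plaque", 3), colnames(second_vals))

  list(
    tx_expr = expression_matrix(tx_vals, condition_of),
    gene_expr = expression_matrix(gene_vals, condition_of),
    de_table = de_table,
    second_expr = expression_matrix(second_vals, second_condition),
    truth = list(
      de_lnc = de_lnc, de_coding = de_coding,
      de_log2fc = de_l2fc,
      minor_isoforms = minor_truth,
      detected_novel = detected_novel,
      lnc_genes = lnc_genes, coding_genes = coding_genes,
      putative_genes = putative_genes
    )
  )
}

#' Generate CAGE peaks, the expression atlas and enhancer/evidence tables
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @param expr Output of [simulate_expression()].
#' @return List: `cage` (peak table), `atlas` (matrix), `enhancers`,
#'   `enhancer_evidence`, `eqtl_links`, `truth` additions (CAGE-matched sets,
#'   planted enrichment, elncRNAs, target pairs, evidenced pairs).
#' @export
simulate_cage_atlas_enhancers <- function(cfg, ann, expr) {
  set.seed(cfg$seed + 2L)
  plan <- ann$truth$gene_plan
  pos <- ann$truth$gene_pos
  lnc <- plan %>%
    filter(.data$type %in% c("lncrna", "novel")) %>%
    left_join(pos %>% select(final_gene = "gene_id", "tss", g_strand = "strand",
                             g_chrom = "chrom"),
              by = "final_gene")

  # CAGE peaks: planted matched fractions per origin, jitter truncated inside
  # the matching window; unmatched genes get either nothing or a decoy peak
  ref_lnc <- lnc %>% filter(.data$type == "lncrna")
  nov_lnc <- lnc %>% filter(.data$type == "novel")
  matched <- c(
    sort(sample(ref_lnc$final_gene,
                round(cfg$cage_fraction_reference * nrow(ref_lnc)))),
    sort(sample(nov_lnc$final_gene,
                round(cfg$cage_fraction_assembled * nrow(nov_lnc))))
  )
  jitter <- function(n) {
    j <- round(stats::rnorm(n, 0, cfg$cage_jitter_sd))
    pmin(pmax(j, -cfg$cage_jitter_max), cfg$cage_jitter_max)
  }
  m <- lnc %>% filter(.data$final_gene %in% matched)
  summit <- m$tss + jitter(nrow(m))
  peaks <- tibble(
    chrom = m$g_chrom, summit = summit, strand = m$g_strand,
    gene = m$final_gene, kind = "matched"
  )
  unmatched <- lnc %>% filter(!.data$final_gene %in% matched)
  decoy_idx <- stats::runif(nrow(unmatched)) < 0.5
  if (any(decoy_idx)) {
    d <- unmatched[decoy_idx, , drop = FALSE]
    peaks <- bind_rows(peaks, tibble(
      chrom = d$g_chrom,
      summit = d$tss + ifelse(d$g_strand == "+", -1L, 1L) *
        sample(150:400, nrow(d), replace = TRUE),
      strand = d$g_strand, gene = d$final_gene, kind = "decoy"
    ))
  }

  # elncRNA plants: CAGE-flag route first (needs matched DE lncRNAs), then
  # enhancer-overlap route from the remaining DE lncRNAs
  de_lnc <- expr$truth$de_lnc
  cage_pool <- intersect(de_lnc, matched)
  if (length(cage_pool) < cfg$n_elnc_cage) {
    stop("infeasible plan: too few CAGE-matched DE lncRNAs for elncRNA plants")
  }
  elnc_cage <- sort(sample(cage_pool, cfg$n_elnc_cage))
  enh_pool <- setdiff(de_lnc, elnc_cage)
  if (length(enh_pool) < cfg$n_elnc_enhancer) {
    stop("infeasible plan: too few DE lncRNAs for enhancer-overlap plants")
  }
  elnc_enh <- sort(sample(enh_pool, cfg$n_elnc_enhancer))

  peaks <- peaks %>%
    mutate(
      flagged = .data$kind == "matched" & .data$gene %in% elnc_cage,
      peak_id = paste0("cage_", dplyr::row_number(),
                       ifelse(.data$flagged, "_elncRNA", "")),
      start = pmax(.data$summit - 10L, 0L),
      end = .data$summit + 10L
    )
  cage <- peaks %>%
    select("chrom", "start", "end", name = "peak_id", "strand") %>%
    mutate(score = "0", .after = "name") %>%
    arrange(.data$chrom, .data$start, .data$name)

  # atlas over CAGE-matched lncRNAs; planted folds realised exactly
  categories <- c(cfg$vsmc_categories, cfg$other_categories)
  atlas_genes <- sort(matched)
  atlas <- matrix(stats::runif(length(atlas_genes) * length(categories), 1, 3),
                  nrow = length(atlas_genes),
                  dimnames = list(atlas_genes, categories))
  n_plant <- length(cfg$enriched_folds)
  plant_genes <- sort(sample(atlas_genes, n_plant))
  plant_cat <- sample(cfg$vsmc_categories, n_plant, replace = TRUE)
  pc <- cfg$atlas_pseudocount
  b <- cfg$atlas_baseline
  for (i in seq_len(n_plant)) {
    atlas[plant_genes[i], ] <- b
    atlas[plant_genes[i], plant_cat[i]] <-
      cfg$enriched_folds[i] * (b + pc) - pc
  }
  enrichment_truth <- tibble(
    gene_id = plant_genes, category = plant_cat, fold = cfg$enriched_folds
  )

  # enhancers over planted elncRNA 5' ends (+ a few intergenic decoys)
  eg <- lnc %>% filter(.data$final_gene %in% elnc_enh)
  enhancers <- tibble(
    chrom = eg$g_chrom,
    start = pmax(eg$tss - 100L, 0L),
    end = eg$tss + 200L,
    name = paste0("GH_", seq_len(nrow(eg))),
    score = "0",
    strand = "."
  )
  site_of <- stats::setNames(enhancers$name, eg$final_gene)
  # decoys live in the always-empty tail of a slot (genes span at most
  # ~17.4 kbp of each slot including the 5' window), so they can never touch
  # a gene's 5' region
  decoy_enh <- tibble(
    chrom = names(cfg$chrom_sizes)[1],
    start = as.integer((0:2) * cfg$slot_spacing + cfg$slot_spacing - 1800L),
    end = as.integer((0:2) * cfg$slot_spacing + cfg$slot_spacing - 1400L),
    name = paste0("GH_decoy_", 1:3), score = "0", strand = "."
  )
  enhancers <- bind_rows(enhancers, decoy_enh)

  # ground-truth target pairs: brute-force double loop over planted DE sets
  elnc_all <- sort(c(elnc_enh, elnc_cage))
  dir_of <- ifelse(expr$truth$de_log2fc > 0, "up", "down")
  de_cod <- expr$truth$de_coding
  cod_pos <- pos %>% filter(.data$gene_id %in% de_cod)
  pairs <- list()
  for (el in elnc_all) {
    el_row <- lnc[lnc$final_gene == el, ]
    for (j in seq_len(nrow(cod_pos))) {
      if (cod_pos$chrom[j] != el_row$g_chrom) next
      dist <- abs(cod_pos$tss[j] - el_row$tss)
      if (dist > cfg$max_target_distance) next
      if (dir_of[[el]] != dir_of[[cod_pos$gene_id[j]]]) next
      pairs[[length(pairs) + 1L]] <- tibble(
        elncrna_gene = el, pcg_gene = cod_pos$gene_id[j],
        distance_bp = dist,
        concordance = ifelse(dir_of[[el]] == "up", "co_induced", "co_repressed")
      )
    }
  }
  target_truth <- bind_rows(pairs) %>%
    arrange(.data$elncrna_gene, .data$pcg_gene)

  # interaction evidence for a planted subset of enhancer-route pairs
  evid_pool <- target_truth %>% filter(.data$elncrna_gene %in% elnc_enh)
  if (nrow(evid_pool) < cfg$n_evidenced_pairs) {
    stop("infeasible plan: only ", nrow(evid_pool),
         " enhancer-route target pairs available for evidence plants")
  }
  evid_rows <- evid_pool[sort(sample.int(nrow(evid_pool),
                                         cfg$n_evidenced_pairs)), ]
  ev_types <- c("capture_hic", "eqtl", "tf_motif", "erna_coexpression")
  enhancer_evidence <- tibble(
    site_id = unname(site_of[evid_rows$elncrna_gene]),
    pcg_id = evid_rows$pcg_gene,
    evidence_type = sample(ev_types, nrow(evid_rows), replace = TRUE)
  )
  eqtl_links <- tibble(
    lncrna_gene = evid_rows$elncrna_gene[seq_len(min(2, nrow(evid_rows)))],
    pcg_gene = evid_rows$pcg_gene[seq_len(min(2, nrow(evid_rows)))]
  )

  list(
    cage = cage,
    atlas = atlas,
    enhancers = enhancers,
    enhancer_evidence = enhancer_evidence,
    eqtl_links = eqtl_links,
    truth = list(
      cage_matched = matched,
      cage_unmatched = sort(unmatched$final_gene),
      enrichment = enrichment_truth,
      elnc_enhancer = elnc_enh,
      elnc_cage = elnc_cage,
      target_pairs = target_truth,
      evidenced_pairs = evid_rows %>%
        select("elncrna_gene", "pcg_gene")
    )
  )
}

#' Generate the full synthetic study, optionally writing all input files
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, writes `ref.gtf`, `asm.gtf`,
#'   `expr.tsv` (transcript level), `gene_expr.tsv`, `samples.tsv`, `de.tsv`,
#'   `cage.bed`, `atlas.tsv`, `enhancers.bed`, `evidence.tsv`, `eqtl.tsv`,
#'   `coding_calls.tsv`, `second_expr.tsv`, `second_samples.tsv`, `truth.json`.
#' @return List with all in-memory components and the combined `truth`.
#' @export
simulate_vsmc_study <- function(cfg = sim_config(), out_dir = NULL) {
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  ext <- simulate_cage_atlas_enhancers(cfg, ann, expr)
  truth <- c(ann$truth, expr$truth, ext$truth)
  study <- list(
    config = cfg,
    reference = ann$reference,
    assembled = ann$assembled,
    coding_calls = ann$coding_calls,
    tx_expr = expr$tx_expr,
    gene_expr = expr$gene_expr,
    de_table = expr$de_table,
    second_expr = expr$second_expr,
    cage = ext$cage,
    atlas = ext$atlas,
    enhancers = ext$enhancers,
    enhancer_evidence = ext$enhancer_evidence,
    eqtl_links = ext$eqtl_links,
    truth = truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_gtf(ann$reference, p("ref.gtf"))
    write_gtf(ann$assembled, p("asm.gtf"))
    write_expr <- function(em, path) {
      tab <- as_tibble(em$values, rownames = "feature_id")
      write_tsv_plain(tab, path)
    }
    write_expr(expr$tx_expr, p("expr.tsv"))
    write_expr(expr$gene_expr, p("gene_expr.tsv"))
    write_tsv_plain(tibble(sample = names(expr$tx_expr$condition_of),
                           condition = unname(expr$tx_expr$condition_of)),
                    p("samples.tsv"))
    write_tsv_plain(expr$de_table, p("de.tsv"))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       ext$cage$chrom, ext$cage$start, ext$cage$end,
                       ext$cage$name, ext$cage$score, ext$cage$strand),
               p("cage.bed"))
    write_tsv_plain(as_tibble(ext$atlas, rownames = "gene_id"), p("atlas.tsv"))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       ext$enhancers$chrom, ext$enhancers$start,
                       ext$enhancers$end, ext$enhancers$name,
                       ext$enhancers$score, ext$enhancers$strand),
               p("enhancers.bed"))
    write_tsv_plain(ext$enhancer_evidence, p("evidence.tsv"))
    write_tsv_plain(ext$eqtl_links, p("eqtl.tsv"))
    write_tsv_plain(ann$coding_calls, p("coding_calls.tsv"))
    write_expr(expr$second_expr, p("second_expr.tsv"))
    write_tsv_plain(tibble(sample = names(expr$second_expr$condition_of),
                           condition = unname(expr$second_expr$condition_of)),
                    p("second_samples.tsv"))
    truth_json <- truth
    truth_json$gene_plan <- NULL  # bulky internals stay in memory only
    truth_json$gene_pos <- NULL
    jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    study$out_dir <- out_dir
  }
  study
}
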