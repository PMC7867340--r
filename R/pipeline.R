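#' Read a sample-to-condition map
#'
#' @param path TSV with columns `sample`, `condition`.
#' @return Named character vector (sample -> condition).
#' @export
read_condition_map <- function(path) {
  tab <- read_table_schema(path, required = c("sample", "condition"))
  stats::setNames(tab$condition, tab$sample)
}

#' Pipeline configuration: every stage threshold in one place
#'
#' @param build A [build_config()].
#' @param classify A [classification_config()].
#' @param de A [de_config()].
#' @param enrichment_threshold Atlas enrichment-fold cut (default 5).
#' @param cage_window_bp CAGE TSS matching half-window (default 50).
#' @param five_prime_window_bp elncRNA 5' region half-width (default 500).
#' @param max_target_distance_bp Target-pairing window (default 250000).
#' @param vsmc_group Atlas categories treated as the VSMC group; default: all
#'   categories whose name starts with `"VSMC"`.
#' @param seed Run seed recorded in the report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(build = build_config(),
                            classify = classification_config(),
                            de = de_config(),
                            enrichment_threshold = 5.0,
                            cage_window_bp = 50L,
                            five_prime_window_bp = 500L,
                            max_target_distance_bp = 250000L,
                            vsmc_group = NULL,
                            seed = 1L) {
  structure(
    list(build = build, classify = classify, de = de,
         enrichment_threshold = enrichment_threshold,
         cage_window_bp = cage_window_bp,
         five_prime_window_bp = five_prime_window_bp,
         max_target_distance_bp = max_target_distance_bp,
         vsmc_group = vsmc_group, seed = seed),
    class = "pipeline_config"
  )
}

#' Detect annotation genes in a second expression dataset
#'
#' A gene is detected when its condition-mean expression exceeds 1 in at least
#' one condition of the second dataset (the robust-expression rule applied to
#' e.g. whole-tissue RNAseq); genes absent from the table count as unobserved.
#'
#' @param gene_ids Genes of the (non-redundant) annotation.
#' @param second_expr An [expression_matrix()] for the second dataset.
#' @param membership Optional tibble `gene_id`, `sources` (list column) for
#'   per-source attribution of detected genes.
#' @return List: `detected` (gene ids), `n_detected`, `fraction`, and, when a
#'   membership map is given, `by_source` counts.
#' @export
detect_in_second_dataset <- function(gene_ids, second_expr, membership = NULL) {
  means <- condition_means(second_expr)
  present <- intersect(gene_ids, rownames(means))
  detected <- robustly_expressed(means[present, , drop = FALSE])
  out <- list(
    detected = sort(detected),
    n_detected = length(detected),
    fraction = length(detected) / length(gene_ids)
  )
  if (!is.null(membership)) {
    src <- membership %>% filter(.data$gene_id %in% detected)
    all_src <- sort(unique(unlist(membership$sources)))
    out$by_source <- vapply(all_src, function(s) {
      sum(vapply(src$sources, function(x) s %in% x, logical(1)))
    }, integer(1))
  }
  out
}

#' Run the full annotation-expansion and characterisation pipeline
#'
#' Orchestrates all stages from input files: reads the reference and assembled
#' GTFs plus expression/DE/CAGE/atlas/enhancer tables, filters the reference,
#' merges in the assembled transcripts with novel-gene naming, classifies
#' genes, applies the expressed/robust filters and the minor-isoform rule,
#' cross-references assembled structures, matches gene TSSs to CAGE peaks,
#' calls cell-type-enriched genes, thresholds differential expression with
#' proportion-enrichment tests and hierarchical clustering, calls elncRNAs and
#' their candidate protein-coding targets, and (optionally) measures detection
#' in a second dataset. Any stage failure aborts with the stage name.
#'
#' @param paths Named list of input paths: `reference_gtf`, `assembled_gtf`,
#'   `expression_tsv` (transcript level), `gene_expression_tsv`, `samples_tsv`,
#'   `de_tsv`, `coding_calls_tsv`, `cage_bed`, `atlas_tsv`, `enhancers_bed`,
#'   `evidence_tsv`; optional `eqtl_tsv`, `second_expression_tsv`,
#'   `second_samples_tsv`, `validation_gtf` (defaults to the reference GTF).
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory for the report JSON and TSVs.
#' @return List report; see the `summary` element for the per-stage counts and
#'   proportion tables.
#' @export
run_pipeline <- function(paths, cfg = pipeline_config(), out_dir = NULL) {
  required <- c("reference_gtf", "assembled_gtf", "expression_tsv",
                "gene_expression_tsv", "samples_tsv", "de_tsv",
                "coding_calls_tsv", "cage_bed", "atlas_tsv", "enhancers_bed",
                "evidence_tsv")
  for (r in required) {
    if (is.null(paths[[r]])) stop("missing input path: ", r)
    if (!file.exists(paths[[r]])) stop("input file not found: ", paths[[r]])
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- inputs -------------------------------------------------------------
  inputs <- stage("read_inputs", {
    condition_of <- read_condition_map(paths$samples_tsv)
    tx_expr <- read_expression_matrix(paths$expression_tsv, condition_of)
    gene_expr <- read_expression_matrix(paths$gene_expression_tsv, condition_of)
    list(
      reference = read_gtf(paths$reference_gtf, origin = "reference"),
      assembled = read_gtf(paths$assembled_gtf, origin = "assembled"),
      tx_expr = tx_expr, gene_expr = gene_expr,
      de_table = read_de_table(paths$de_tsv),
      coding_calls = read_table_schema(paths$coding_calls_tsv,
                                       required = c("transcript_id", "call")),
      cage = read_cage_bed(paths$cage_bed),
      atlas = read_atlas(paths$atlas_tsv),
      enhancers = read_bed(paths$enhancers_bed),
      evidence = read_table_schema(paths$evidence_tsv,
                                   required = c("site_id", "pcg_id",
                                                "evidence_type")),
      eqtl = if (!is.null(paths$eqtl_tsv))
        read_table_schema(paths$eqtl_tsv,
                          required = c("lncrna_gene", "pcg_gene")) else NULL
    )
  })

  ## --- build: filter reference, merge assembled ---------------------------
  built <- stage("transcriptome_build", {
    tx_means_all <- rowMeans(inputs$tx_expr$values)
    ref_plain <- inputs$reference %>% select(-"origin")
    asm_plain <- inputs$assembled %>% select(-"origin")
    filtered_ref <- filter_reference(ref_plain, tx_means_all, cfg$build)
    merged <- merge_transcriptomes(asm_plain, filtered_ref, cfg$build)
    list(filtered_ref = filtered_ref, merged = merged,
         n_reference_in = length(unique(ref_plain$transcript_id)),
         n_reference_kept = length(unique(filtered_ref$transcript_id)))
  })
  merged <- built$merged$exons

  ## --- classification ------------------------------------------------------
  classed <- stage("lncrna_annotation", {
    calls <- merged %>%
      distinct(.data$transcript_id, .data$gene_id) %>%
      left_join(inputs$coding_calls %>% select("transcript_id", "call"),
                by = "transcript_id")
    if (anyNA(calls$call)) {
      stop("transcript(s) without a coding call: ",
           paste(utils::head(calls$transcript_id[is.na(calls$call)], 3),
                 collapse = ", "))
    }
    classify_genes(calls)
  })
  lnc_genes_all <- classed$gene_id[classed$classification == "lncRNA"]

  ## --- expression filters --------------------------------------------------
  exprsets <- stage("expression_filters", {
    tx_means <- condition_means(inputs$tx_expr)
    gene_means <- condition_means(inputs$gene_expr)
    expressed_tx <- filter_expressed(tx_means, cfg$classify)
    robust_genes <- robustly_expressed(gene_means)
    # minor-isoform rule on newly assembled lncRNA genes
    origin_of <- stats::setNames(
      c(rep("reference", length(unique(inputs$reference$transcript_id))),
        rep("assembled", length(unique(inputs$assembled$transcript_id)))),
      c(unique(inputs$reference$transcript_id),
        unique(inputs$assembled$transcript_id))
    )
    tx_tbl <- merged %>% distinct(.data$transcript_id, .data$gene_id)
    asm_lnc_genes <- tx_tbl %>%
      filter(.data$gene_id %in% lnc_genes_all,
             origin_of[.data$transcript_id] == "assembled") %>%
      dplyr::pull(.data$gene_id) %>% unique()
    tx_total <- rowSums(inputs$tx_expr$values)
    dropped <- character()
    for (g in asm_lnc_genes) {
      members <- tx_tbl$transcript_id[tx_tbl$gene_id == g]
      expr_g <- tx_total[members]
      expr_g[is.na(expr_g)] <- 0
      names(expr_g) <- members
      kept <- filter_minor_isoforms(expr_g, cfg$classify)
      dropped <- c(dropped, setdiff(members, kept))
    }
    list(tx_means = tx_means, gene_means = gene_means,
         expressed_tx = expressed_tx, robust_genes = robust_genes,
         minor_dropped = dropped, origin_of = origin_of)
  })
  annotation <- merged %>%
    filter(!.data$transcript_id %in% exprsets$minor_dropped)

  gene_origin <- annotation %>%
    distinct(.data$transcript_id, .data$gene_id) %>%
    mutate(origin = unname(exprsets$origin_of[.data$transcript_id])) %>%
    group_by(.data$gene_id) %>%
    summarise(origin = if (all(.data$origin == "assembled")) "assembled"
              else "reference", .groups = "drop")
  novel_genes <- gene_origin$gene_id[gene_origin$origin == "assembled"]
  lnc_robust <- intersect(lnc_genes_all, exprsets$robust_genes)

  ## --- structure validation ------------------------------------------------
  validation <- stage("structure_validation", {
    val_path <- if (!is.null(paths$validation_gtf)) paths$validation_gtf else
      paths$reference_gtf
    val_ann <- read_gtf(val_path)
    queries <- annotation %>%
      filter(.data$gene_id %in% lnc_robust,
             .data$transcript_id %in% exprsets$expressed_tx)
    matches <- match_structures(
      queries %>% select("chrom", "start", "end", "strand",
                         "transcript_id", "gene_id"),
      val_ann
    )
    origin_lab <- exprsets$origin_of[matches$query_id]
    summary <- if (nrow(matches) > 0) {
      summarize_match_classes(matches, origin_lab)
    } else NULL
    list(matches = matches, summary = summary)
  })

  ## --- CAGE matching -------------------------------------------------------
  cage_res <- stage("cage_matching", {
    genes <- gene_summary(annotation %>% filter(.data$gene_id %in% lnc_robust))
    cm <- match_cage(genes, inputs$cage, cfg$cage_window_bp)
    # 5' completeness of CAGE-matched genes (gap = summit upstream of TSS)
    tss_tx <- transcript_summary(
      annotation %>% filter(.data$gene_id %in% lnc_robust)
    ) %>%
      group_by(.data$gene_id) %>%
      arrange(dplyr::desc(.data$strand == "-"), .by_group = TRUE) %>%
      summarise(first_exon_length = {
        i <- if (first(.data$strand) == "-") which.max(.data$tx_end)
        else which.min(.data$tx_start)
        .data$first_exon_length[i]
      }, .groups = "drop")
    comp <- cm %>%
      filter(.data$cage_matched) %>%
      left_join(tss_tx, by = "gene_id") %>%
      mutate(incompleteness = five_prime_completeness(
        .data$summit_distance, .data$first_exon_length))
    list(matches = cm, genes = genes,
         completeness = comp %>% select("gene_id", "incompleteness"),
         median_incompleteness = stats::median(comp$incompleteness))
  })
  cage_matched_genes <- cage_res$matches$gene_id[cage_res$matches$cage_matched]

  ## --- cell-type enrichment ------------------------------------------------
  enrich <- stage("cell_enrichment", {
    group <- cfg$vsmc_group
    if (is.null(group)) {
      group <- grep("^VSMC", colnames(inputs$atlas), value = TRUE)
    }
    genes <- intersect(cage_matched_genes, rownames(inputs$atlas))
    calls <- call_enriched(inputs$atlas, genes, group,
                           threshold = cfg$enrichment_threshold)
    list(calls = calls, group = group,
         enriched = calls$gene_id[calls$enriched])
  })

  ## --- differential expression ---------------------------------------------
  de_res <- stage("expression_analysis", {
    de <- threshold_de(inputs$de_table, cfg$de)
    de_genes <- de$gene_id[de$de]
    de_lnc <- intersect(de_genes, lnc_robust)
    expressed_lnc <- lnc_robust
    prop_novel_de <- if (length(de_lnc) > 0) {
      proportion_enrichment(novel_genes, de_lnc, expressed_lnc)
    } else NULL
    clusters <- if (length(de_lnc) >= cfg$de$n_clusters) {
      keep <- intersect(de_genes, rownames(exprsets$gene_means))
      cluster_de_genes(exprsets$gene_means[keep, , drop = FALSE],
                       cfg$de$n_clusters)
    } else NULL
    list(de = de, de_genes = de_genes, de_lnc = de_lnc,
         prop_novel_de = prop_novel_de, clusters = clusters)
  })

  ## --- elncRNAs and candidate targets --------------------------------------
  elnc_res <- stage("enhancer_targets", {
    lnc_gene_tbl <- cage_res$genes
    elnc <- call_elncrnas(lnc_gene_tbl, inputs$enhancers, cage_res$matches,
                          cfg$five_prime_window_bp)
    elnc_genes <- elnc$gene_id[elnc$elncrna]
    de_dir <- stats::setNames(de_res$de$direction, de_res$de$gene_id)
    de_elnc <- intersect(elnc_genes, de_res$de_genes)
    elnc_de_tbl <- lnc_gene_tbl %>%
      filter(.data$gene_id %in% de_elnc) %>%
      mutate(direction = unname(de_dir[.data$gene_id]))
    coding_genes <- classed$gene_id[classed$classification == "coding"]
    pcg_tbl <- gene_summary(annotation %>%
                              filter(.data$gene_id %in% coding_genes)) %>%
      mutate(de = .data$gene_id %in% de_res$de_genes,
             direction = ifelse(.data$de, unname(de_dir[.data$gene_id]), "none"))
    pairs <- find_candidate_targets(elnc_de_tbl, pcg_tbl,
                                    cfg$max_target_distance_bp)
    ev <- join_interaction_evidence(
      pairs,
      elnc %>% select("gene_id", "enhancer_sites"),
      inputs$evidence, inputs$eqtl,
      known_genes = unique(annotation$gene_id)
    )
    prop_novel_elnc <- if (length(elnc_genes) > 0) {
      proportion_enrichment(novel_genes, elnc_genes, lnc_robust)
    } else NULL
    list(elnc = elnc, elnc_genes = elnc_genes, de_elnc = de_elnc,
         pairs = ev$pairs, evidenced = ev$evidenced,
         prop_novel_elnc = prop_novel_elnc)
  })

  ## --- optional second-dataset detection -----------------------------------
  second <- NULL
  if (!is.null(paths$second_expression_tsv)) {
    second <- stage("second_dataset", {
      cond2 <- read_condition_map(paths$second_samples_tsv)
      expr2 <- read_expression_matrix(paths$second_expression_tsv, cond2)
      detect_in_second_dataset(novel_genes, expr2)
    })
  }

  report <- list(
    config = cfg,
    seed = cfg$seed,
    summary = list(
      n_reference_transcripts_in = built$n_reference_in,
      n_reference_transcripts_kept = built$n_reference_kept,
      n_merged_transcripts = length(unique(annotation$transcript_id)),
      n_genes = length(unique(annotation$gene_id)),
      n_novel_genes = length(novel_genes),
      n_lncrna_genes = length(lnc_genes_all),
      n_robust_lncrna_genes = length(lnc_robust),
      n_expressed_transcripts = length(exprsets$expressed_tx),
      n_minor_isoforms_dropped = length(exprsets$minor_dropped),
      n_cage_matched = length(cage_matched_genes),
      cage_matched_fraction =
        length(cage_matched_genes) / max(length(lnc_robust), 1),
      median_five_prime_incompleteness = cage_res$median_incompleteness,
      n_vsmc_enriched = length(enrich$enriched),
      n_de_genes = length(de_res$de_genes),
      n_de_lncrna = length(de_res$de_lnc),
      novel_fraction_of_de_lnc =
        if (!is.null(de_res$prop_novel_de))
          de_res$prop_novel_de$fraction_foreground else NA,
      novel_fraction_of_expressed_lnc =
        if (!is.null(de_res$prop_novel_de))
          de_res$prop_novel_de$fraction_background else NA,
      fisher_p_novel_de =
        if (!is.null(de_res$prop_novel_de)) de_res$prop_novel_de$p_value else NA,
      n_elncrna = length(elnc_res$elnc_genes),
      n_de_elncrna = length(elnc_res$de_elnc),
      n_target_pairs = nrow(elnc_res$pairs),
      n_evidenced_pairs = nrow(elnc_res$evidenced),
      second_dataset = if (!is.null(second))
        second[c("n_detected", "fraction")] else NULL
    ),
    annotation = annotation,
    gene_classification = classed,
    novel_genes = sort(novel_genes),
    structure_matches = validation$matches,
    structure_summary = validation$summary,
    cage_matches = cage_res$matches,
    enrichment_calls = enrich$calls,
    de_calls = de_res$de,
    de_clusters = de_res$clusters,
    elncrnas = elnc_res$elnc,
    target_pairs = elnc_res$pairs,
    evidenced_pairs = elnc_res$evidenced,
    second_dataset = second
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(annotation, file.path(out_dir, "annotation.gtf"))
    write_tsv_plain(classed, file.path(out_dir, "gene_classification.tsv"))
    write_tsv_plain(validation$matches, file.path(out_dir, "structure_matches.tsv"))
    write_tsv_plain(cage_res$matches, file.path(out_dir, "cage_matches.tsv"))
    write_tsv_plain(enrich$calls, file.path(out_dir, "enrichment_calls.tsv"))
    write_tsv_plain(de_res$de, file.path(out_dir, "de_calls.tsv"))
    if (!is.null(de_res$clusters)) {
      write_tsv_plain(de_res$clusters, file.path(out_dir, "de_clusters.tsv"))
    }
    write_tsv_plain(
      elnc_res$pairs %>%
        mutate(evidence = vapply(.data$evidence, paste, character(1),
                                 collapse = ",")),
      file.path(out_dir, "target_pairs.tsv")
    )
    report_json <- report
    report_json$annotation <- NULL
    report_json$config <- unclass(cfg)
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}
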