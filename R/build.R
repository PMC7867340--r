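#' Configuration for reference filtering and transcriptome merging
#'
#' Defaults follow the upstream assembly protocol: transcripts shorter than
#' 300 bp are removed, spliced (>= 2 exon) transcripts require >= 0.5 FPKM and
#' unspliced (single-exon) transcripts >= 1 FPKM; novel genes receive numeric
#' identifiers under the assembler-style "MSTRG." prefix.
#'
#' @param min_transcript_length Minimum transcript length in bp.
#' @param min_fpkm_spliced Minimum FPKM for multi-exon transcripts.
#' @param min_fpkm_unspliced Minimum FPKM for single-exon transcripts.
#' @param novel_prefix Identifier prefix for novel genes.
#' @return List of class `build_config`.
#' @export
build_config <- function(min_transcript_length = 300L,
                         min_fpkm_spliced = 0.5,
                         min_fpkm_unspliced = 1.0,
                         novel_prefix = "MSTRG.") {
  stopifnot(min_transcript_length > 0, min_fpkm_spliced > 0,
            min_fpkm_unspliced > 0, nzchar(novel_prefix))
  structure(
    list(
      min_transcript_length = as.integer(min_transcript_length),
      min_fpkm_spliced = min_fpkm_spliced,
      min_fpkm_unspliced = min_fpkm_unspliced,
      novel_prefix = novel_prefix
    ),
    class = "build_config"
  )
}

#' Filter a reference transcript set before merging
#'
#' A transcript is retained iff its length is at least
#' `min_transcript_length` and its FPKM is at least `min_fpkm_spliced` (>= 2
#' exons) or `min_fpkm_unspliced` (single exon). Transcripts without an
#' expression value are treated as 0 FPKM.
#'
#' @param exons Reference exon table.
#' @param fpkm Named numeric vector of per-transcript FPKM.
#' @param cfg A [build_config()].
#' @return Filtered exon table (possibly empty).
#' @export
filter_reference <- function(exons, fpkm, cfg = build_config()) {
  validate_exons(exons)
  tx <- transcript_summary(exons)
  expr <- fpkm[tx$transcript_id]
  expr[is.na(expr)] <- 0
  spliced <- tx$n_exons >= 2L
  keep_expr <- ifelse(spliced, expr >= cfg$min_fpkm_spliced,
                      expr >= cfg$min_fpkm_unspliced)
  keep <- tx$length >= cfg$min_transcript_length & keep_expr
  exons %>% filter(.data$transcript_id %in% tx$transcript_id[keep])
}

## Internal: per-transcript intron-chain key ("" for monoexonic transcripts).
chain_keys <- function(exons) {
  exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_exons = n(),
      chain = if (n() < 2) NA_character_ else {
        paste0(first(.data$chrom), first(.data$strand), ":",
               paste(utils::head(.data$end, -1), utils::tail(.data$start, -1),
                     sep = "-", collapse = ","))
      },
      .groups = "drop"
    )
}

#' Merge assembled transcripts into a filtered reference annotation
#'
#' Reproduces the merge step that yields an expanded transcriptome:
#' * an assembled multi-exon transcript whose intron chain exactly equals a
#'   reference transcript's is redundant and dropped (the reference copy wins);
#' * an assembled transcript sharing >= 1 exonic base on the same strand with a
#'   reference gene becomes a novel isoform of that gene;
#' * remaining assembled transcripts form novel genes named
#'   `novel_prefix` + serial, numbered in (chrom, start) genome order.
#'
#' @param assembled Exon table of assembled transcripts.
#' @param reference Exon table of (already filtered) reference transcripts.
#' @param cfg A [build_config()]; assembled transcripts shorter than
#'   `min_transcript_length` are rejected (assembler contract re-checked).
#' @param dataset_tag Label stored on the result for cross-dataset attribution.
#' @return List of class `expanded_transcriptome`: `exons` (with `origin`
#'   column) and `dataset_tag`.
#' @export
merge_transcriptomes <- function(assembled, reference, cfg = build_config(),
                                 dataset_tag = "dataset") {
  validate_exons(assembled)
  validate_exons(reference)
  shared <- intersect(unique(assembled$transcript_id),
                      unique(reference$transcript_id))
  if (length(shared) > 0) {
    stop("transcript id collision between assembled and reference: ",
         paste(utils::head(shared, 3), collapse = ", "))
  }
  asm_tx <- transcript_summary(assembled)
  if (any(asm_tx$length < cfg$min_transcript_length)) {
    stop("assembled transcript(s) below minimum length: ",
         paste(utils::head(
           asm_tx$transcript_id[asm_tx$length < cfg$min_transcript_length], 3
         ), collapse = ", "))
  }

  ref_chain <- chain_keys(reference)
  asm_chain <- chain_keys(assembled)
  redundant <- asm_chain$transcript_id[
    !is.na(asm_chain$chain) & asm_chain$chain %in% ref_chain$chain
  ]
  asm_keep <- assembled %>% filter(!.data$transcript_id %in% redundant)

  ref_out <- reference
  ref_out$origin <- "reference"
  asm_gene <- tibble(transcript_id = character(), gene_id = character())

  if (nrow(asm_keep) > 0) {
    # attach to a same-strand reference gene when exonic overlap >= 1 bp
    asm_gr <- exons_to_granges(asm_keep)
    ref_gr <- exons_to_granges(reference)
    hits <- GenomicRanges::findOverlaps(asm_gr, ref_gr, ignore.strand = FALSE)
    if (length(hits) > 0) {
      ov <- tibble(
        transcript_id = asm_gr$transcript_id[S4Vectors::queryHits(hits)],
        ref_gene = ref_gr$gene_id[S4Vectors::subjectHits(hits)],
        width = IRanges::width(IRanges::pintersect(
          IRanges::ranges(asm_gr)[S4Vectors::queryHits(hits)],
          IRanges::ranges(ref_gr)[S4Vectors::subjectHits(hits)]
        ))
      ) %>%
        group_by(.data$transcript_id, .data$ref_gene) %>%
        summarise(width = sum(.data$width), .groups = "drop") %>%
        group_by(.data$transcript_id) %>%
        arrange(dplyr::desc(.data$width), .data$ref_gene, .by_group = TRUE) %>%
        summarise(gene_id = first(.data$ref_gene), .groups = "drop")
      asm_gene <- ov
    }
  }

  attached <- asm_keep %>%
    filter(.data$transcript_id %in% asm_gene$transcript_id) %>%
    select(-"gene_id") %>%
    left_join(asm_gene, by = "transcript_id")

  novel <- asm_keep %>% filter(!.data$transcript_id %in% asm_gene$transcript_id)
  if (nrow(novel) > 0) {
    novel_genes <- novel %>%
      group_by(.data$gene_id) %>%
      summarise(chrom = min(.data$chrom), start = min(.data$start),
                .groups = "drop") %>%
      arrange(.data$chrom, .data$start, .data$gene_id) %>%
      mutate(new_id = paste0(cfg$novel_prefix, dplyr::row_number()))
    novel <- novel %>%
      left_join(novel_genes %>% select("gene_id", "new_id"), by = "gene_id") %>%
      mutate(gene_id = .data$new_id) %>%
      select(-"new_id")
  }

  asm_out <- bind_rows(attached, novel)
  if (nrow(asm_out) > 0) asm_out$origin <- "assembled"
  exons <- bind_rows(
    ref_out %>% select("chrom", "start", "end", "strand",
                       "transcript_id", "gene_id", "origin"),
    asm_out %>% select(any_of(c("chrom", "start", "end", "strand",
                                "transcript_id", "gene_id", "origin")))
  ) %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)
  structure(
    list(exons = exons, dataset_tag = dataset_tag),
    class = "expanded_transcriptome"
  )
}

#' Build a non-redundant union of expanded transcriptomes
#'
#' Transcripts with identical intron chains (multi-exon) collapse to one record
#' whose terminal exon boundaries are the union across sources (5'-most start,
#' 3'-most end); single-exon transcripts collapse when their reciprocal overlap
#' is at least `mono_reciprocal_overlap` on the same strand. Merged transcripts
#' are re-grouped into union genes (same-strand exonic overlap) named
#' `NR.<serial>` in genome order, and a membership map records which source
#' dataset(s) contributed each union gene.
#'
#' @param transcriptomes List of `expanded_transcriptome` objects (>= 2, or a
#'   single one for idempotence checks).
#' @param mono_reciprocal_overlap Reciprocal-overlap fraction for single-exon
#'   redundancy (default 0.5).
#' @return List: `exons` (union annotation with union `gene_id`s),
#'   `membership` (tibble gene_id x sources), `transcript_sources`.
#' @export
build_union <- function(transcriptomes, mono_reciprocal_overlap = 0.5) {
  stopifnot(length(transcriptomes) >= 1)
  pooled <- bind_rows(lapply(transcriptomes, function(t) {
    ex <- t$exons
    ex$source <- t$dataset_tag
    ex$uid <- paste0(t$dataset_tag, "|", ex$transcript_id)
    ex
  }))
  # naming-convention guard: sources must agree on chromosome style
  chroms <- lapply(transcriptomes, function(t) unique(t$exons$chrom))
  prefixed <- vapply(chroms, function(cc) all(grepl("^chr", cc)), logical(1))
  if (length(unique(prefixed)) > 1) {
    stop("chromosome naming mismatch across inputs (mixed 'chr' prefix); ",
         "offending sources: ",
         paste(vapply(transcriptomes[prefixed != prefixed[1]],
                      function(t) t$dataset_tag, character(1)), collapse = ", "))
  }
  # transcript-level summaries with chain keys
  tx <- pooled %>%
    rename(orig_tx = "transcript_id") %>%
    mutate(transcript_id = .data$uid)
  ck <- chain_keys(tx %>% select("chrom", "start", "end", "strand",
                                 "transcript_id", "gene_id"))
  sm <- transcript_summary(tx %>% select("chrom", "start", "end", "strand",
                                         "transcript_id", "gene_id")) %>%
    left_join(ck %>% select("transcript_id", "chain"), by = "transcript_id")

  # group multi-exon transcripts by chain; single-exon by reciprocal overlap
  sm$group <- NA_integer_
  multi <- !is.na(sm$chain)
  if (any(multi)) {
    sm$group[multi] <- match(sm$chain[multi], unique(sm$chain[multi]))
  }
  n_multi_groups <- length(unique(stats::na.omit(sm$group)))
  mono <- sm[!multi, , drop = FALSE]
  if (nrow(mono) > 0) {
    gr <- GenomicRanges::GRanges(mono$chrom,
                                 IRanges::IRanges(mono$tx_start + 1L, mono$tx_end),
                                 strand = mono$strand)
    hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[q],
                                            IRanges::ranges(gr)[s]))
    ok <- w >= mono_reciprocal_overlap * IRanges::width(IRanges::ranges(gr)[q]) &
      w >= mono_reciprocal_overlap * IRanges::width(IRanges::ranges(gr)[s])
    comp <- connected_components(nrow(mono), q[ok], s[ok])
    sm$group[!multi] <- n_multi_groups + comp
  }

  # one representative transcript per group; terminal boundaries = union
  rep_tbl <- sm %>%
    group_by(.data$group) %>%
    summarise(
      rep_uid = min(.data$transcript_id),
      new_start = min(.data$tx_start),
      new_end = max(.data$tx_end),
      members = list(unique(.data$transcript_id)),
      .groups = "drop"
    )
  rep_exons <- tx %>%
    filter(.data$transcript_id %in% rep_tbl$rep_uid)
  # stretch the representative's terminal exons to the union boundaries
  rep_exons <- rep_exons %>%
    left_join(sm %>% select("transcript_id", "group"), by = "transcript_id") %>%
    left_join(rep_tbl %>% select("group", "new_start", "new_end"), by = "group") %>%
    group_by(.data$transcript_id) %>%
    mutate(
      start = ifelse(.data$start == min(.data$start), .data$new_start, .data$start),
      end = ifelse(.data$end == max(.data$end), .data$new_end, .data$end)
    ) %>%
    ungroup()

  # union genes: same-strand exonic overlap among representatives
  rgr <- exons_to_granges(rep_exons)
  ghits <- GenomicRanges::findOverlaps(rgr, rgr, ignore.strand = FALSE)
  qi <- match(rgr$transcript_id[S4Vectors::queryHits(ghits)], rep_tbl$rep_uid)
  si <- match(rgr$transcript_id[S4Vectors::subjectHits(ghits)], rep_tbl$rep_uid)
  gene_comp <- connected_components(nrow(rep_tbl), qi, si)
  rep_tbl$gene_group <- gene_comp

  gene_order <- rep_exons %>%
    left_join(rep_tbl %>% select("group", "gene_group"), by = "group") %>%
    group_by(.data$gene_group) %>%
    summarise(chrom = min(.data$chrom), start = min(.data$start), .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$gene_group) %>%
    mutate(union_gene = paste0("NR.", dplyr::row_number()))

  rep_tbl <- rep_tbl %>%
    left_join(gene_order %>% select("gene_group", "union_gene"), by = "gene_group")

  out_exons <- rep_exons %>%
    left_join(rep_tbl %>% select("group", "union_gene"), by = "group") %>%
    mutate(gene_id = .data$union_gene) %>%
    select("chrom", "start", "end", "strand", "transcript_id", "gene_id") %>%
    arrange(.data$chrom, .data$start, .data$transcript_id)

  src_of_uid <- stats::setNames(tx$source[!duplicated(tx$transcript_id)],
                                tx$transcript_id[!duplicated(tx$transcript_id)])
  transcript_sources <- rep_tbl %>%
    mutate(sources = lapply(.data$members, function(m) sort(unique(unname(src_of_uid[m]))))) %>%
    select(transcript_id = "rep_uid", gene_id = "union_gene", "sources")
  membership <- transcript_sources %>%
    group_by(.data$gene_id) %>%
    summarise(sources = list(sort(unique(unlist(.data$sources)))), .groups = "drop")

  list(exons = out_exons, membership = membership,
       transcript_sources = transcript_sources)
}

## Internal: union-find connected components for n nodes and edge lists.
connected_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[min(a, b)] <- parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
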