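#' Extract the intron chain of a transcript
#'
#' The intron chain is the ordered list of (donor_end, acceptor_start)
#' splice-junction coordinate pairs of a multi-exon transcript, on the internal
#' 0-based half-open scale. Identical chains define the same splicing
#' structure.
#'
#' @param exons Exon table restricted to one transcript.
#' @return Tibble with `donor_end`, `acceptor_start` (0 rows for a monoexonic
#'   transcript), plus attributes `chrom` and `strand`.
#' @export
extract_intron_chain <- function(exons) {
  validate_exons(exons)
  if (length(unique(exons$transcript_id)) != 1) {
    stop("extract_intron_chain expects exons of exactly one transcript")
  }
  exons <- exons %>% arrange(.data$start)
  if (nrow(exons) < 2) {
    out <- tibble(donor_end = integer(), acceptor_start = integer())
  } else {
    out <- tibble(
      donor_end = utils::head(exons$end, -1),
      acceptor_start = utils::tail(exons$start, -1)
    )
  }
  attr(out, "chrom") <- exons$chrom[1]
  attr(out, "strand") <- exons$strand[1]
  out
}

## Internal: per-transcript junction table (one row per junction).
junction_table <- function(exons) {
  exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      donor_end = list(utils::head(.data$end, -1)),
      acceptor_start = list(utils::tail(.data$start, -1)),
      .groups = "drop"
    ) %>%
    tidyr::unnest(c("donor_end", "acceptor_start")) %>%
    mutate(junction = paste0(.data$chrom, .data$strand, ":",
                             .data$donor_end, "-", .data$acceptor_start))
}

#' Cross-reference transcript structures against an independent annotation
#'
#' Classifies each query transcript against a reference annotation:
#' `full_chain` when a same-strand reference transcript carries the exact same
#' chain of introns; otherwise `partial_junction` when at least one splice
#' junction (donor/acceptor coordinate pair) is shared with any same-strand
#' reference transcript; otherwise `no_match`. Monoexonic queries use an
#' exonic-overlap rule instead: `full_chain` when a same-strand monoexonic
#' reference transcript overlaps reciprocally by at least
#' `mono_reciprocal_overlap`, `partial_junction` on any same-strand exonic
#' overlap, else `no_match`. Unstranded (`.`) queries are skipped with a
#' warning.
#'
#' @param queries Exon table of query transcripts.
#' @param reference Exon table of the independent annotation.
#' @param mono_reciprocal_overlap Reciprocal-overlap threshold for monoexonic
#'   queries (default 0.8).
#' @return Tibble: `query_id`, `match_class`, `best_reference_id` (the
#'   full-chain match, or the reference transcript sharing most junctions /
#'   most overlap; NA for `no_match`).
#' @export
match_structures <- function(queries, reference, mono_reciprocal_overlap = 0.8) {
  validate_exons(queries)
  validate_exons(reference)
  if (any(queries$strand == ".")) {
    warning("skipping unstranded query transcript(s) from structure matching")
    queries <- queries %>% filter(.data$strand != ".")
  }
  q_sum <- transcript_summary(queries)
  r_sum <- transcript_summary(reference)
  q_chain <- chain_keys(queries)
  r_chain <- chain_keys(reference)

  out <- tibble(
    query_id = q_sum$transcript_id,
    match_class = "no_match",
    best_reference_id = NA_character_
  )

  # full chain: exact chain-key identity (multi-exon)
  r_multi <- r_chain %>% filter(!is.na(.data$chain))
  full_map <- r_multi %>%
    group_by(.data$chain) %>%
    summarise(ref_id = min(.data$transcript_id), .groups = "drop")
  qm <- q_chain %>%
    filter(!is.na(.data$chain)) %>%
    left_join(full_map, by = "chain")
  full_ids <- qm$transcript_id[!is.na(qm$ref_id)]
  out$match_class[out$query_id %in% full_ids] <- "full_chain"
  out$best_reference_id[match(qm$transcript_id[!is.na(qm$ref_id)], out$query_id)] <-
    qm$ref_id[!is.na(qm$ref_id)]

  # partial: >= 1 shared junction, best reference = most shared junctions
  q_j <- junction_table(queries) %>% filter(!.data$transcript_id %in% full_ids)
  r_j <- junction_table(reference)
  if (nrow(q_j) > 0 && nrow(r_j) > 0) {
    shared <- q_j %>%
      inner_join(r_j %>% select(ref_id = "transcript_id", "junction"),
                 by = "junction", relationship = "many-to-many") %>%
      group_by(.data$transcript_id, .data$ref_id) %>%
      summarise(n_shared = n(), .groups = "drop") %>%
      group_by(.data$transcript_id) %>%
      arrange(dplyr::desc(.data$n_shared), .data$ref_id, .by_group = TRUE) %>%
      summarise(ref_id = first(.data$ref_id), .groups = "drop")
    hit <- match(shared$transcript_id, out$query_id)
    out$match_class[hit] <- "partial_junction"
    out$best_reference_id[hit] <- shared$ref_id
  }

  # monoexonic queries: reciprocal-overlap rule
  q_mono <- q_sum %>% filter(.data$n_exons == 1L)
  if (nrow(q_mono) > 0 && nrow(r_sum) > 0) {
    qgr <- GenomicRanges::GRanges(q_mono$chrom,
                                  IRanges::IRanges(q_mono$tx_start + 1L, q_mono$tx_end),
                                  strand = q_mono$strand)
    ref_ex <- reference %>% filter(.data$strand != ".")
    rgr <- exons_to_granges(ref_ex)
    hits <- GenomicRanges::findOverlaps(qgr, rgr, ignore.strand = FALSE)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- tibble(
        query_id = q_mono$transcript_id[qh],
        ref_id = rgr$transcript_id[sh],
        width = IRanges::width(IRanges::pintersect(
          IRanges::ranges(qgr)[qh], IRanges::ranges(rgr)[sh]))
      ) %>%
        group_by(.data$query_id, .data$ref_id) %>%
        summarise(width = sum(.data$width), .groups = "drop")
      best_partial <- ov %>%
        group_by(.data$query_id) %>%
        arrange(dplyr::desc(.data$width), .data$ref_id, .by_group = TRUE) %>%
        summarise(ref_id = first(.data$ref_id), .groups = "drop")
      hit <- match(best_partial$query_id, out$query_id)
      out$match_class[hit] <- "partial_junction"
      out$best_reference_id[hit] <- best_partial$ref_id

      # upgrade to full_chain on reciprocal overlap with a monoexonic reference tx
      r_mono <- r_sum %>% filter(.data$n_exons == 1L)
      recip <- ov %>%
        filter(.data$ref_id %in% r_mono$transcript_id) %>%
        left_join(q_mono %>% mutate(q_len = .data$tx_end - .data$tx_start) %>%
                    select(query_id = "transcript_id", "q_len"), by = "query_id") %>%
        left_join(r_mono %>% mutate(r_len = .data$tx_end - .data$tx_start) %>%
                    select(ref_id = "transcript_id", "r_len"), by = "ref_id") %>%
        filter(.data$width >= mono_reciprocal_overlap * .data$q_len,
               .data$width >= mono_reciprocal_overlap * .data$r_len) %>%
        group_by(.data$query_id) %>%
        arrange(dplyr::desc(.data$width), .data$ref_id, .by_group = TRUE) %>%
        summarise(ref_id = first(.data$ref_id), .groups = "drop")
      if (nrow(recip) > 0) {
        hit <- match(recip$query_id, out$query_id)
        out$match_class[hit] <- "full_chain"
        out$best_reference_id[hit] <- recip$ref_id
      }
    }
  }
  out
}

#' Summarise structure-match classes by transcript origin
#'
#' @param matches Output of [match_structures()].
#' @param origin_of Named character vector: query_id -> origin
#'   (`"reference"`/`"assembled"`).
#' @return Tibble of per-origin class proportions (rows sum to 1); origins
#'   with no queries are omitted with a warning.
#' @export
summarize_match_classes <- function(matches, origin_of) {
  matches$origin <- unname(origin_of[matches$query_id])
  if (anyNA(matches$origin)) {
    stop("query transcript(s) without an origin label")
  }
  empty <- setdiff(unique(unname(origin_of)), unique(matches$origin))
  if (length(empty) > 0) {
    warning("origin class(es) with no queries omitted: ",
            paste(empty, collapse = ", "))
  }
  matches %>%
    group_by(.data$origin, .data$match_class) %>%
    summarise(n = n(), .groups = "drop_last") %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Match gene TSSs to CAGE peaks
#'
#' A gene is CAGE-matched when a same-strand peak summit lies within
#' `window_bp` of the gene TSS (5'-most transcript start on the gene strand).
#' Unstranded peaks or genes are skipped with a warning.
#'
#' @param genes Gene table from [gene_summary()] (needs `gene_id`, `chrom`,
#'   `strand`, `tss`).
#' @param peaks CAGE peak table from [read_cage_bed()].
#' @param window_bp Matching half-window around the TSS (default 50).
#' @return Tibble: `gene_id`, `cage_matched`, `best_peak` (nearest summit),
#'   `summit_distance` (signed, positive = summit upstream of the TSS),
#'   `elncrna_flag` of the best peak.
#' @export
match_cage <- function(genes, peaks, window_bp = 50L) {
  if (any(genes$strand == ".") || any(peaks$strand == ".")) {
    warning("skipping unstranded gene(s)/peak(s) in CAGE matching")
    genes <- genes %>% filter(.data$strand != ".")
    peaks <- peaks %>% filter(.data$strand != ".")
  }
  cand <- genes %>%
    select("gene_id", "chrom", "strand", "tss") %>%
    inner_join(peaks %>% select("chrom", "strand", "peak_id", "summit",
                                "elncrna_flag"),
               by = c("chrom", "strand"), relationship = "many-to-many") %>%
    mutate(
      # orientation-corrected: positive = summit upstream of the TSS
      signed_dist = ifelse(.data$strand == "+",
                           .data$tss - .data$summit,
                           .data$summit - .data$tss)
    ) %>%
    filter(abs(.data$signed_dist) <= window_bp) %>%
    group_by(.data$gene_id) %>%
    arrange(abs(.data$signed_dist), .data$peak_id, .by_group = TRUE) %>%
    summarise(best_peak = first(.data$peak_id),
              summit_distance = first(.data$signed_dist),
              elncrna_flag = first(.data$elncrna_flag),
              .groups = "drop")
  genes %>%
    select("gene_id") %>%
    left_join(cand, by = "gene_id") %>%
    mutate(cage_matched = !is.na(.data$best_peak)) %>%
    select("gene_id", "cage_matched", "best_peak", "summit_distance",
           "elncrna_flag")
}

#' 5' incompleteness fraction of a transcript against its CAGE summit
#'
#' The gap is the distance by which the CAGE summit lies upstream of the
#' transcript 5' end (0 when the summit is at or downstream of the start); the
#' incompleteness fraction is `gap / (gap + first_exon_length)`, i.e. the
#' fraction of the CAGE-corrected first-exon extent that the annotation is
#' missing.
#'
#' @param upstream_gap Nonnegative upstream distance(s) in bp (signed
#'   distances are clamped at 0, i.e. summits downstream of the start count
#'   as complete).
#' @param first_exon_length First-exon length(s) in bp.
#' @return Numeric vector of fractions in `[0, 1)`.
#' @export
five_prime_completeness <- function(upstream_gap, first_exon_length) {
  stopifnot(all(first_exon_length > 0))
  gap <- pmax(upstream_gap, 0)
  gap / (gap + first_exon_length)
}
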