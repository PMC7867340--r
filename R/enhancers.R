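#' Call enhancer-transcribed lncRNAs (elncRNAs)
#'
#' A lncRNA gene is an elncRNA when its 5' region (an orientation-agnostic
#' window of `five_prime_window_bp` each side of the TSS) overlaps at least
#' one enhancer interval, or when its matched CAGE peak carries the elncRNA
#' class flag.
#'
#' @param genes Gene table from [gene_summary()] restricted to lncRNA genes.
#' @param enhancers Tibble of enhancer intervals (`chrom`, `start`, `end`,
#'   optional `name` used as site id).
#' @param cage_matches Output of [match_cage()] for the same genes (used for
#'   the elncRNA CAGE flag); may be NULL.
#' @param five_prime_window_bp Half-width of the 5' region (default 500).
#' @return Tibble: `gene_id`, `elncrna` (logical), `source`
#'   (`"enhancer_overlap"`, `"cage_flag"`, `"both"` or NA), `enhancer_sites`
#'   (list of overlapping site ids).
#' @export
call_elncrnas <- function(genes, enhancers, cage_matches = NULL,
                          five_prime_window_bp = 500L) {
  region_start <- pmax(genes$tss - five_prime_window_bp, 0L)
  region_end <- genes$tss + five_prime_window_bp
  site_id <- if ("name" %in% names(enhancers)) enhancers$name else
    paste0("enh", seq_len(nrow(enhancers)))
  overlap_sites <- vector("list", nrow(genes))
  if (nrow(enhancers) > 0 && nrow(genes) > 0) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(region_start + 1L, region_end))
    egr <- GenomicRanges::GRanges(enhancers$chrom,
                                  IRanges::IRanges(enhancers$start + 1L, enhancers$end))
    hits <- GenomicRanges::findOverlaps(ggr, egr, ignore.strand = TRUE)
    for (i in seq_along(hits)) {
      q <- S4Vectors::queryHits(hits)[i]
      overlap_sites[[q]] <- c(overlap_sites[[q]],
                              site_id[S4Vectors::subjectHits(hits)[i]])
    }
  }
  has_enh <- lengths(overlap_sites) > 0
  has_flag <- rep(FALSE, nrow(genes))
  if (!is.null(cage_matches)) {
    flag_of <- stats::setNames(
      cage_matches$cage_matched & !is.na(cage_matches$elncrna_flag) &
        cage_matches$elncrna_flag,
      cage_matches$gene_id
    )
    fl <- unname(flag_of[genes$gene_id])
    has_flag <- !is.na(fl) & fl
  }
  src <- rep(NA_character_, nrow(genes))
  src[has_enh & !has_flag] <- "enhancer_overlap"
  src[!has_enh & has_flag] <- "cage_flag"
  src[has_enh & has_flag] <- "both"
  tibble(
    gene_id = genes$gene_id,
    elncrna = has_enh | has_flag,
    source = src,
    enhancer_sites = lapply(overlap_sites, function(s) sort(unique(s)))
  )
}

#' Find candidate co-regulated protein-coding targets of DE elncRNAs
#'
#' Pairs each differentially expressed elncRNA with every protein-coding gene
#' on the same chromosome whose TSS lies within `max_distance_bp`
#' (TSS-to-TSS, inclusive) and that is differentially expressed in the same
#' direction; pairs are labelled `co_induced` (both up) or `co_repressed`
#' (both down). Enhancer action is modelled as cis only: no trans pairs.
#'
#' @param elncrnas Tibble of DE elncRNA genes: `gene_id`, `chrom`, `tss`,
#'   `direction` (`"up"`/`"down"`).
#' @param pcgs Tibble of protein-coding genes: `gene_id`, `chrom`, `tss`,
#'   `de` (logical), `direction`.
#' @param max_distance_bp Maximum TSS-to-TSS distance (default 250000).
#' @return Tibble of target pairs: `elncrna_gene`, `pcg_gene`, `distance_bp`,
#'   `concordance`.
#' @export
find_candidate_targets <- function(elncrnas, pcgs, max_distance_bp = 250000L) {
  pairs <- elncrnas %>%
    select(elncrna_gene = "gene_id", "chrom", elnc_tss = "tss",
           elnc_dir = "direction") %>%
    inner_join(
      pcgs %>% filter(.data$de) %>%
        select(pcg_gene = "gene_id", "chrom", pcg_tss = "tss",
               pcg_dir = "direction"),
      by = "chrom", relationship = "many-to-many"
    ) %>%
    mutate(distance_bp = abs(.data$elnc_tss - .data$pcg_tss)) %>%
    filter(.data$distance_bp <= max_distance_bp,
           .data$elnc_dir == .data$pcg_dir,
           .data$elnc_dir %in% c("up", "down")) %>%
    mutate(concordance = ifelse(.data$elnc_dir == "up",
                                "co_induced", "co_repressed")) %>%
    select("elncrna_gene", "pcg_gene", "distance_bp", "concordance") %>%
    arrange(.data$elncrna_gene, .data$pcg_gene)
  pairs
}

#' Join enhancer/eQTL interaction evidence onto candidate target pairs
#'
#' Annotates each pair with the union of evidence types connecting the
#' elncRNA's overlapping enhancer site(s) to the paired PCG (from the
#' enhancer-evidence table) plus any direct lncRNA-PCG eQTL links. Evidence
#' rows referencing genes absent from the pair list are skipped with a
#' warning only when they name an unknown gene id.
#'
#' @param pairs Output of [find_candidate_targets()].
#' @param elnc_sites Tibble `gene_id`, `enhancer_sites` (list column) from
#'   [call_elncrnas()].
#' @param enhancer_evidence Tibble `site_id`, `pcg_id`, `evidence_type` with
#'   types in capture_hic / eqtl / tf_motif / erna_coexpression.
#' @param eqtl_links Optional tibble `lncrna_gene`, `pcg_gene` of direct eQTL
#'   associations (evidence type `eqtl`).
#' @param known_genes Optional character vector used to detect evidence rows
#'   referencing unknown genes.
#' @return List: `pairs` (with `evidence` list column) and `evidenced`
#'   (pairs with >= 1 evidence type).
#' @export
join_interaction_evidence <- function(pairs, elnc_sites, enhancer_evidence,
                                      eqtl_links = NULL, known_genes = NULL) {
  allowed <- c("capture_hic", "eqtl", "tf_motif", "erna_coexpression")
  if (nrow(enhancer_evidence) > 0 &&
      !all(enhancer_evidence$evidence_type %in% allowed)) {
    stop("unknown evidence type: ",
         paste(setdiff(enhancer_evidence$evidence_type, allowed), collapse = ", "))
  }
  if (!is.null(known_genes) && nrow(enhancer_evidence) > 0) {
    unknown <- !enhancer_evidence$pcg_id %in% known_genes
    if (any(unknown)) {
      warning("skipping ", sum(unknown),
              " evidence row(s) referencing unknown gene(s)")
      enhancer_evidence <- enhancer_evidence[!unknown, , drop = FALSE]
    }
  }
  sites_of <- stats::setNames(elnc_sites$enhancer_sites, elnc_sites$gene_id)
  evidence <- lapply(seq_len(nrow(pairs)), function(i) {
    el <- pairs$elncrna_gene[i]
    pcg <- pairs$pcg_gene[i]
    ev <- character()
    sites <- sites_of[[el]]
    if (!is.null(sites) && length(sites) > 0 && nrow(enhancer_evidence) > 0) {
      hit <- enhancer_evidence$site_id %in% sites &
        enhancer_evidence$pcg_id == pcg
      ev <- c(ev, enhancer_evidence$evidence_type[hit])
    }
    if (!is.null(eqtl_links) && nrow(eqtl_links) > 0) {
      if (any(eqtl_links$lncrna_gene == el & eqtl_links$pcg_gene == pcg)) {
        ev <- c(ev, "eqtl")
      }
    }
    sort(unique(ev))
  })
  pairs$evidence <- evidence
  list(pairs = pairs, evidenced = pairs[lengths(evidence) > 0, , drop = FALSE])
}
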