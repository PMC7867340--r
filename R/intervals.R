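#' @importFrom dplyr %>% arrange group_by summarise ungroup mutate filter select
#'   left_join inner_join distinct bind_rows first n rename all_of any_of across
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

VALID_STRANDS <- c("+", "-", ".")

#' Validate an exon table
#'
#' The package represents transcript models as flat "exon tables": one row per
#' exon with columns `chrom`, `start`, `end`, `strand`, `transcript_id` and
#' `gene_id` (plus optional extras such as `origin`). Coordinates are 0-based
#' half-open everywhere inside the package; conversion to/from the 1-based GTF
#' convention happens only in [read_gtf()] / [write_gtf()].
#'
#' @param exons A data frame of exons.
#' @return The validated exon table (invisibly coerced to a tibble).
#' @export
validate_exons <- function(exons) {
  required <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0) {
    stop("exon table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(exons$start < 0)) stop("exon start coordinates must be >= 0")
  if (any(exons$end <= exons$start)) {
    stop("exon end must be > start (0-based half-open)")
  }
  if (!all(exons$strand %in% VALID_STRANDS)) {
    stop("strand must be one of '+', '-', '.'")
  }
  bad <- exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      one_chrom = length(unique(.data$chrom)) == 1L,
      one_strand = length(unique(.data$strand)) == 1L,
      disjoint = {
        o <- order(.data$start)
        all(diff(.data$start[o]) > 0) &&
          all(utils::head(.data$end[o], -1) <= utils::tail(.data$start[o], -1))
      },
      .groups = "drop"
    ) %>%
    filter(!.data$one_chrom | !.data$one_strand | !.data$disjoint)
  if (nrow(bad) > 0) {
    stop(
      "invalid transcript(s) (mixed chrom/strand or overlapping exons): ",
      paste(utils::head(bad$transcript_id, 5), collapse = ", ")
    )
  }
  invisible(as_tibble(exons))
}

#' Summarise an exon table to one row per transcript
#'
#' @param exons Exon table (see [validate_exons()]).
#' @return Tibble with one row per transcript: span, exon count, summed exonic
#'   length, the strand-aware TSS coordinate (`start` on `+`, `end` on `-`,
#'   both on the internal 0-based half-open scale) and the 5'-most exon length.
#'   An `origin` column is carried through when present.
#' @export
transcript_summary <- function(exons) {
  exons <- as_tibble(exons)
  has_origin <- "origin" %in% names(exons)
  out <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      n_exons = n(),
      length = sum(.data$end - .data$start),
      tss = if (first(.data$strand) == "-") max(.data$end) else min(.data$start),
      first_exon_length = if (first(.data$strand) == "-") {
        (.data$end - .data$start)[which.max(.data$start)]
      } else {
        (.data$end - .data$start)[which.min(.data$start)]
      },
      origin = if (has_origin) first(.data$origin) else NA_character_,
      .groups = "drop"
    )
  if (!has_origin) out$origin <- NULL
  out
}

#' Summarise genes: span and strand-aware TSS (5'-most transcript start)
#'
#' @param exons Exon table.
#' @return Tibble with one row per gene (`gene_id`, `chrom`, `strand`, `tss`).
#' @export
gene_summary <- function(exons) {
  tx <- transcript_summary(exons)
  tx %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      gene_start = min(.data$tx_start),
      gene_end = max(.data$tx_end),
      tss = if (first(.data$strand) == "-") max(.data$tx_end) else min(.data$tx_start),
      .groups = "drop"
    )
}

## Internal: exon table -> GRanges (shifts to 1-based for IRanges arithmetic).
exons_to_granges <- function(exons) {
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = exons$gene_id
  )
}
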