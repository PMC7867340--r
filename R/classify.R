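#' Configuration for expression-based transcript/gene classification
#'
#' @param min_condition_fpkm Expressed-transcript threshold: a feature is
#'   expressed if its mean FPKM reaches this value in at least one condition.
#' @param minor_isoform_fraction Minor-isoform cut: isoforms contributing less
#'   than this fraction of a gene's total isoform expression are discarded.
#' @param per_condition Compute the minor-isoform fraction per condition
#'   (maximum over conditions) instead of on the all-sample total.
#' @return List of class `classification_config`.
#' @export
classification_config <- function(min_condition_fpkm = 1.0,
                                  minor_isoform_fraction = 0.10,
                                  per_condition = FALSE) {
  stopifnot(min_condition_fpkm > 0,
            minor_isoform_fraction > 0, minor_isoform_fraction < 1)
  structure(
    list(min_condition_fpkm = min_condition_fpkm,
         minor_isoform_fraction = minor_isoform_fraction,
         per_condition = per_condition),
    class = "classification_config"
  )
}

#' Per-condition mean expression
#'
#' @param expr An [expression_matrix()].
#' @return Numeric matrix, features x conditions, of sample means.
#' @export
condition_means <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  conds <- unique(unname(expr$condition_of))
  if (length(conds) < 1) stop("expression matrix has no conditions")
  out <- vapply(conds, function(cc) {
    cols <- names(expr$condition_of)[expr$condition_of == cc]
    if (length(cols) == 0) stop("condition with 0 samples: ", cc)
    rowMeans(expr$values[, cols, drop = FALSE])
  }, numeric(nrow(expr$values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(expr$values), conds))
  out
}

#' Expressed-feature filter
#'
#' A feature is expressed if its condition-mean FPKM is at least
#' `min_condition_fpkm` in one or more conditions.
#'
#' @param means Feature x condition matrix from [condition_means()].
#' @param cfg A [classification_config()].
#' @return Character vector of expressed feature ids.
#' @export
filter_expressed <- function(means, cfg = classification_config()) {
  rownames(means)[apply(means, 1, max) >= cfg$min_condition_fpkm]
}

#' Robustly expressed genes across one or more datasets
#'
#' A gene is robustly expressed if its condition-mean FPKM is strictly greater
#' than 1 in at least one condition of any dataset.
#'
#' @param means_list List of feature x condition mean matrices (one per
#'   dataset), or a single matrix.
#' @param threshold Strict threshold (default 1).
#' @return Character vector of robustly expressed gene ids.
#' @export
robustly_expressed <- function(means_list, threshold = 1.0) {
  if (is.matrix(means_list)) means_list <- list(means_list)
  ids <- unique(unlist(lapply(means_list, rownames)))
  robust <- vapply(ids, function(g) {
    any(vapply(means_list, function(m) {
      g %in% rownames(m) && max(m[g, ]) > threshold
    }, logical(1)))
  }, logical(1))
  ids[robust]
}

#' Remove minor isoforms of a gene
#'
#' Discards isoforms whose expression is less than
#' `minor_isoform_fraction` of the summed expression of all the gene's
#' isoforms. The maximally expressed isoform is always retained, so a gene is
#' never emptied. Intended for newly assembled lncRNA genes.
#'
#' @param isoform_expr Named numeric vector: total expression per isoform of
#'   one gene (summed over all samples by the caller unless a per-condition
#'   variant is wanted).
#' @param cfg A [classification_config()].
#' @return Character vector of retained isoform ids.
#' @export
filter_minor_isoforms <- function(isoform_expr, cfg = classification_config()) {
  if (length(isoform_expr) == 0) return(character())
  total <- sum(isoform_expr)
  if (total <= 0) {
    warning("gene with all-zero isoform expression: retaining all isoforms")
    return(names(isoform_expr))
  }
  keep <- isoform_expr >= cfg$minor_isoform_fraction * total
  if (!any(keep)) keep[which.max(isoform_expr)] <- TRUE
  names(isoform_expr)[keep]
}

#' Classify a gene from its transcripts' coding calls
#'
#' Gene-level hierarchy: any coding transcript makes the gene `coding`;
#' otherwise any putative-lncRNA transcript makes it `putative_lncRNA`;
#' otherwise (all transcripts high-confidence lncRNA) the gene is `lncRNA`.
#'
#' @param calls Character vector of per-transcript calls, each one of
#'   `"coding"`, `"putative_lncRNA"`, `"high_confidence_lncRNA"`.
#' @return One of `"coding"`, `"putative_lncRNA"`, `"lncRNA"`.
#' @export
classify_gene <- function(calls) {
  allowed <- c("coding", "putative_lncRNA", "high_confidence_lncRNA")
  if (length(calls) == 0) stop("gene with no transcript calls")
  unknown <- setdiff(calls, allowed)
  if (length(unknown) > 0) {
    stop("unknown transcript coding call: ", paste(unique(unknown), collapse = ", "))
  }
  if (any(calls == "coding")) return("coding")
  if (any(calls == "putative_lncRNA")) return("putative_lncRNA")
  "lncRNA"
}

#' Classify all genes from a transcript-call table
#'
#' @param tx_calls Tibble with `transcript_id`, `gene_id`, `call`.
#' @return Tibble with `gene_id`, `classification`.
#' @export
classify_genes <- function(tx_calls) {
  tx_calls %>%
    group_by(.data$gene_id) %>%
    summarise(classification = classify_gene(.data$call), .groups = "drop")
}

#' Heuristic ORF-based coding call
#'
#' Stand-in default when externally computed coding-potential calls are not
#' supplied: scans the three forward reading frames of the (stranded)
#' transcript sequence for the longest ATG-initiated, stop-terminated open
#' reading frame, and calls the transcript coding when that ORF reaches
#' `min_orf_aa` codons (stop excluded).
#'
#' @param sequence Nucleotide string over A/C/G/T/N (the transcript strand).
#' @param min_orf_aa Minimum ORF length in amino acids (default 100).
#' @return `"coding"` or `"noncoding"`.
#' @export
orf_coding_call <- function(sequence, min_orf_aa = 100L) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a nonempty nucleotide string")
  }
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTN characters")
  if (longest_orf_aa(s) >= min_orf_aa) "coding" else "noncoding"
}

#' Longest ORF length (amino acids) over the three forward frames
#'
#' @param sequence Nucleotide string (transcript strand).
#' @return Integer: codons between an ATG and the next in-frame stop,
#'   stop codon excluded; 0 when no complete ORF exists.
#' @export
longest_orf_aa <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    codons <- substring(s, starts, starts + 2)
    open_at <- NA_integer_  # index (in codons) of the current ORF's ATG
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}
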