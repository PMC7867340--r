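#' Per-category enrichment values for a gene in an expression atlas
#'
#' For each cell category c, the enrichment fold is the gene's expression in c
#' relative to the arithmetic mean of its expression in all other categories
#' (leave-one-out), with a pseudocount guarding zeros:
#' `fold(c) = (x_c + pc) / (mean(x_{-c}) + pc)`.
#'
#' @param atlas Gene x category numeric matrix (categories with replicate
#'   samples are assumed pre-averaged into one column each).
#' @param gene Gene id (must be a rowname of `atlas`).
#' @param pseudocount Positive pseudocount (default 0.1).
#' @param other_summary How to summarise the other categories: `"mean"`
#'   (default) or `"median"`.
#' @return Named numeric vector of folds, one per category.
#' @export
enrichment_values <- function(atlas, gene, pseudocount = 0.1,
                              other_summary = c("mean", "median")) {
  other_summary <- match.arg(other_summary)
  stopifnot(pseudocount > 0, ncol(atlas) >= 2)
  if (!gene %in% rownames(atlas)) stop("gene absent from atlas: ", gene)
  x <- atlas[gene, ]
  k <- length(x)
  others <- if (other_summary == "mean") {
    (sum(x) - x) / (k - 1)
  } else {
    vapply(seq_len(k), function(i) stats::median(x[-i]), numeric(1))
  }
  (x + pseudocount) / (others + pseudocount)
}

#' Maximum enrichment fold of a gene over a category group
#'
#' @param atlas Gene x category matrix.
#' @param gene Gene id.
#' @param group Character vector of category names (e.g. the VSMC subtypes).
#' @param ... Passed to [enrichment_values()].
#' @return Numeric scalar: max fold over the group's categories.
#' @export
max_group_enrichment <- function(atlas, gene, group, ...) {
  unknown <- setdiff(group, colnames(atlas))
  if (length(unknown) > 0) {
    stop("unknown atlas category: ", paste(unknown, collapse = ", "))
  }
  if (length(group) == 0) stop("category group is empty")
  max(enrichment_values(atlas, gene, ...)[group])
}

#' Call cell-type-enriched genes
#'
#' A gene is enriched when its enrichment fold reaches `threshold` in at least
#' one category of the group (default 5-fold, the atlas convention for
#' cell-type-enriched expression).
#'
#' @param atlas Gene x category matrix.
#' @param genes Gene ids to evaluate (default: all atlas genes).
#' @param group Category group (e.g. VSMC subtypes).
#' @param threshold Enrichment-fold threshold (default 5).
#' @param ... Passed to [enrichment_values()].
#' @return Tibble: `gene_id`, `max_fold`, `enriched`.
#' @export
call_enriched <- function(atlas, genes = rownames(atlas), group,
                          threshold = 5.0, ...) {
  folds <- vapply(genes, function(g) max_group_enrichment(atlas, g, group, ...),
                  numeric(1))
  tibble(gene_id = genes, max_fold = unname(folds),
         enriched = unname(folds) >= threshold)
}
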