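#' Configuration for differential-expression thresholds and clustering
#'
#' @param min_abs_fc Minimum absolute fold change, linear scale (default 1.5;
#'   applied as a strict `>` on `|log2fc| > log2(min_abs_fc)`).
#' @param max_pvalue Strict p-value cut-off (default 0.05, raw p).
#' @param n_clusters Number of expression clusters to cut the tree at
#'   (default 6).
#' @param adjust Apply Benjamini-Hochberg adjustment to the p-values before
#'   thresholding (off by default; the stated cut-off is on raw p).
#' @return List of class `de_config`.
#' @export
de_config <- function(min_abs_fc = 1.5, max_pvalue = 0.05, n_clusters = 6L,
                      adjust = FALSE) {
  stopifnot(min_abs_fc > 1, max_pvalue > 0, max_pvalue < 1, n_clusters >= 2)
  structure(
    list(min_abs_fc = min_abs_fc, max_pvalue = max_pvalue,
         n_clusters = as.integer(n_clusters), adjust = adjust),
    class = "de_config"
  )
}

#' Threshold a differential-expression table
#'
#' A gene is differentially expressed iff `|log2fc| > log2(min_abs_fc)` and
#' `pvalue < max_pvalue`, both strict. Records with missing statistics are
#' excluded with a warning.
#'
#' @param records Tibble with `gene_id`, `log2fc`, `pvalue`.
#' @param cfg A [de_config()].
#' @return Tibble: `gene_id`, `log2fc`, `pvalue`, `de` (logical), `direction`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
threshold_de <- function(records, cfg = de_config()) {
  bad <- !is.finite(records$log2fc) | !is.finite(records$pvalue)
  if (any(bad)) {
    warning("excluding ", sum(bad), " gene(s) with missing DE statistics")
    records <- records[!bad, , drop = FALSE]
  }
  p <- if (cfg$adjust) stats::p.adjust(records$pvalue, "BH") else records$pvalue
  de <- abs(records$log2fc) > log2(cfg$min_abs_fc) & p < cfg$max_pvalue
  tibble(
    gene_id = records$gene_id,
    log2fc = records$log2fc,
    pvalue = records$pvalue,
    de = de,
    direction = ifelse(!de, "none", ifelse(records$log2fc > 0, "up", "down"))
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by hypergeometric enumeration: with margins
#' fixed, it sums the probabilities of all tables whose probability does not
#' exceed that of the observed table (standard two-sided definition, with the
#' customary `1 + 1e-7` relative tolerance on the tie comparison).
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = feature in/out of
#'   the subset, columns = condition membership.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be nonnegative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("all-zero contingency table")
  m <- a + b        # row-1 margin
  k <- a + c        # column-1 margin
  lo <- max(0L, k - (n - m))
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n - m, k)
  p_obs <- stats::dhyper(a, m, n - m, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Proportion-enrichment test of a gene subset in a foreground vs background
#'
#' Tests whether a subset (e.g. newly assembled lncRNA genes) is
#' over-represented among a foreground set (e.g. differentially expressed
#' lncRNAs) relative to a background (e.g. all expressed lncRNAs), via
#' Fisher's exact test on the 2x2 table (subset-in-foreground,
#' foreground-not-subset, subset-in-rest-of-background, rest-not-subset).
#'
#' @param subset,foreground,background Character vectors of gene ids;
#'   `foreground` must be a subset of `background`.
#' @return List: `fraction_foreground` (share of foreground in the subset),
#'   `fraction_background` (share of the whole background in the subset),
#'   `p_value`, `table` (the 2x2 counts).
#' @export
proportion_enrichment <- function(subset, foreground, background) {
  if (length(foreground) == 0) stop("empty foreground set")
  if (length(setdiff(foreground, background)) > 0) {
    stop("foreground must be a subset of background")
  }
  rest <- setdiff(background, foreground)
  a <- length(intersect(subset, foreground))
  b <- length(setdiff(foreground, subset))
  c <- length(intersect(subset, rest))
  d <- length(setdiff(rest, subset))
  list(
    fraction_foreground = a / length(foreground),
    fraction_background = length(intersect(subset, background)) / length(background),
    p_value = fisher_exact_2x2(a, b, c, d),
    table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("foreground", "rest"),
                                   c("in_subset", "not_subset")))
  )
}

#' Hierarchically cluster DE genes on their condition-mean profiles
#'
#' Per-gene z-scores of the condition means are clustered by agglomerative
#' hierarchical clustering (Ward linkage on Euclidean distance) and the tree
#' is cut at `k` clusters. Zero-variance profiles are z-scored to all-zero
#' with a warning.
#'
#' @param means Gene x condition matrix of condition means (DE genes only).
#' @param k Number of clusters.
#' @return Tibble: `gene_id`, `cluster` (1..k, relabelled in order of first
#'   appearance for determinism).
#' @export
cluster_de_genes <- function(means, k) {
  if (nrow(means) < k) {
    stop("fewer genes (", nrow(means), ") than clusters (", k, ")")
  }
  z <- t(apply(means, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  if (any(apply(means, 1, stats::sd) == 0)) {
    warning("zero-variance expression profile(s): z-scored to 0")
  }
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  tibble(gene_id = rownames(means), cluster = relabel)
}

#' Simple per-gene differential-expression summary (not a count model)
#'
#' A deliberately plain two-group comparison for self-contained synthetic
#' runs: per gene, a Welch t-test on log2(FPKM + 1) with the mean log2
#' difference reported as `log2fc`. This is not a negative-binomial count
#' model; outputs are tagged `method = "welch_log2"` so they cannot be
#' mistaken for DESeq2 statistics.
#'
#' @param expr An [expression_matrix()].
#' @param condition_a,condition_b The two condition labels to compare
#'   (log2fc is b relative to a).
#' @return Tibble: `gene_id`, `log2fc`, `pvalue`, `flag`
#'   (`"zero_variance"` where the test is degenerate and p is set to 1),
#'   with attribute `method`.
#' @export
simple_de_stub <- function(expr, condition_a, condition_b) {
  stopifnot(inherits(expr, "expr_matrix"))
  sa <- names(expr$condition_of)[expr$condition_of == condition_a]
  sb <- names(expr$condition_of)[expr$condition_of == condition_b]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("need >= 2 samples per condition")
  }
  la <- log2(expr$values[, sa, drop = FALSE] + 1)
  lb <- log2(expr$values[, sb, drop = FALSE] + 1)
  res <- lapply(seq_len(nrow(la)), function(i) {
    fc <- mean(lb[i, ]) - mean(la[i, ])
    if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) {
      list(fc = fc, p = 1, flag = "zero_variance")
    } else {
      p <- tryCatch(stats::t.test(lb[i, ], la[i, ])$p.value,
                    error = function(e) NA_real_)
      if (is.na(p)) list(fc = fc, p = 1, flag = "zero_variance")
      else list(fc = fc, p = p, flag = "")
    }
  })
  out <- tibble(
    gene_id = rownames(expr$values),
    log2fc = vapply(res, `[[`, numeric(1), "fc"),
    pvalue = vapply(res, `[[`, numeric(1), "p"),
    flag = vapply(res, `[[`, character(1), "flag")
  )
  attr(out, "method") <- "welch_log2"
  out
}
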