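#' Read exon features from a GTF file
#'
#' Parses `exon` features into the package's internal exon-table representation.
#' GTF coordinates (1-based, inclusive) are converted to the internal 0-based
#' half-open convention at this boundary and nowhere else. Both the GENCODE
#' attribute dialect (`key "value";`) and the `key=value` dialect are accepted;
#' [write_gtf()] always emits the GENCODE dialect.
#'
#' @param path Path to a GTF file.
#' @param origin Optional origin label (`"reference"` or `"assembled"`) stored
#'   in an `origin` column on every exon.
#' @return An exon table (see [validate_exons()]), exons sorted by position
#'   within each transcript.
#' @export
read_gtf <- function(path, origin = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), transcript_id = character(), gene_id = character()
    )
    if (!is.null(origin)) out$origin <- character()
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF line ", idx[which(nf < 9)[1]], ": expected 9 tab-separated fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) {
    stop("no exon features found in ", path)
  }
  m <- m[is_exon, , drop = FALSE]
  line_no <- idx[is_exon]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    stop("malformed GTF line ", line_no[which(is.na(start1) | is.na(end1))[1]],
         ": non-numeric coordinates")
  }
  tx_id <- gtf_attribute(m[, 9], "transcript_id")
  g_id <- gtf_attribute(m[, 9], "gene_id")
  if (anyNA(tx_id)) {
    stop("exon without transcript_id attribute at line ", line_no[which(is.na(tx_id))[1]])
  }
  if (anyNA(g_id)) {
    stop("exon without gene_id attribute at line ", line_no[which(is.na(g_id))[1]])
  }
  out <- tibble(
    chrom = m[, 1],
    start = start1 - 1L,  # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = m[, 7],
    transcript_id = tx_id,
    gene_id = g_id
  )
  if (!is.null(origin)) out$origin <- origin
  out <- out %>% arrange(.data$chrom, .data$transcript_id, .data$start)
  validate_exons(out)
  out
}

## Internal: pull one attribute from GTF column-9 strings, either dialect.
gtf_attribute <- function(attrs, key) {
  # GENCODE dialect: key "value";  GFF3-ish dialect: key=value (; separated)
  pat_gencode <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  pat_gff3 <- paste0('(^|;)\\s*', key, '\\s*=\\s*"?([^";]*)"?')
  val <- rep(NA_character_, length(attrs))
  m1 <- regmatches(attrs, regexec(pat_gencode, attrs))
  hit1 <- lengths(m1) == 3
  val[hit1] <- vapply(m1[hit1], `[`, character(1), 3)
  m2 <- regmatches(attrs[!hit1], regexec(pat_gff3, attrs[!hit1]))
  hit2 <- lengths(m2) == 3
  val[!hit1][hit2] <- vapply(m2[hit2], `[`, character(1), 3)
  val
}

#' Write an exon table to GTF (GENCODE attribute dialect)
#'
#' Emits one `exon` feature per row in canonical order (chrom, transcript
#' start, transcript_id, exon start), converting internal 0-based half-open
#' coordinates back to 1-based inclusive GTF coordinates. Writing then
#' re-reading is lossless for coordinates, strand and identifiers, and the
#' canonical ordering makes output byte-stable.
#'
#' @param exons Exon table.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lncforge") {
  validate_exons(exons)
  tx <- transcript_summary(exons) %>% select("transcript_id", "tx_start")
  ord <- exons %>%
    left_join(tx, by = "transcript_id") %>%
    arrange(.data$chrom, .data$tx_start, .data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ord$chrom, source, ord$start + 1L, ord$end, ord$strand,
    ord$gene_id, ord$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
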