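#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open, which matches the package's internal convention,
#' so no coordinate shift is applied. Columns beyond the first three (name,
#' score, strand) are retained when present.
#'
#' @param path Path to a BED file (3-6 columns, no header).
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  ncol <- min(c(nf, 6L))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  out <- tibble(
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end = suppressWarnings(as.integer(get(3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("malformed BED line ", which(is.na(out$start) | is.na(out$end))[1],
         ": non-numeric coordinates")
  }
  bad <- which(out$end <= out$start)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], ": end <= start")
  }
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- get(5)
  if (ncol >= 6) {
    out$strand <- get(6)
    if (!all(out$strand %in% VALID_STRANDS)) {
      stop("malformed BED strand value: ", setdiff(out$strand, VALID_STRANDS)[1])
    }
  }
  out
}

#' Read CAGE peaks from BED into a peak table with summits
#'
#' The summit is taken as the interval midpoint (integer floor). Peaks whose
#' name column contains the token `elncRNA` are flagged as enhancer-derived
#' CAGE sites, mirroring FANTOM CAT's elncRNA class labels.
#'
#' @param path Path to a BED6 file of CAGE peaks.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `peak_id`, `summit`,
#'   `elncrna_flag`.
#' @export
read_cage_bed <- function(path) {
  bed <- read_bed(path)
  if (!all(c("name", "strand") %in% names(bed))) {
    stop("CAGE BED must have at least 6 columns (name and strand required)")
  }
  tibble(
    chrom = bed$chrom,
    start = bed$start,
    end = bed$end,
    strand = bed$strand,
    peak_id = bed$name,
    summit = bed$start + (bed$end - bed$start) %/% 2L,
    elncrna_flag = grepl("elncRNA", bed$name, fixed = TRUE)
  )
}

#' Read a TSV table with a required-column schema
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numeric; a non-numeric cell
#'   raises an error naming the first offending row.
#' @return Tibble with all columns of the file.
#' @export
read_table_schema <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(tab))) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed) & !is.na(tab[[col]]) & tab[[col]] != "NA")
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " of ", path)
    }
    tab[[col]] <- parsed
  }
  tab
}

#' Read a differential-expression statistics table
#'
#' Expects DESeq2-style per-gene statistics (consumed, not computed): columns
#' `gene_id`, `log2fc`, `pvalue`.
#'
#' @param path Path to the TSV.
#' @return Tibble of DE records.
#' @export
read_de_table <- function(path) {
  read_table_schema(path, required = c("gene_id", "log2fc", "pvalue"),
                    numeric_cols = c("log2fc", "pvalue"))
}

#' Read an expression matrix (features x samples) plus sample-condition map
#'
#' @param path TSV with a `feature_id` column followed by one column per sample.
#' @param condition_of Named character vector mapping sample name to condition.
#' @return List with `values` (numeric matrix, rownames = features),
#'   `condition_of`, and `unit`.
#' @param unit Expression unit label, `"FPKM"` (default) or `"TPM"`.
#' @export
read_expression_matrix <- function(path, condition_of, unit = "FPKM") {
  tab <- read_table_schema(path, required = "feature_id")
  samples <- setdiff(names(tab), "feature_id")
  if (length(samples) == 0) stop("expression table has no sample columns")
  tab <- read_table_schema(path, required = "feature_id", numeric_cols = samples)
  values <- as.matrix(tab[samples])
  rownames(values) <- tab$feature_id
  expression_matrix(values, condition_of, unit = unit)
}

#' Construct/validate an expression matrix object
#'
#' @param values Nonnegative numeric matrix, features x samples.
#' @param condition_of Named character vector mapping each sample (column) to
#'   exactly one condition label.
#' @param unit `"FPKM"` or `"TPM"`.
#' @return List of class `expr_matrix`.
#' @export
expression_matrix <- function(values, condition_of, unit = "FPKM") {
  unit <- match.arg(unit, c("FPKM", "TPM"))
  if (any(values < 0)) stop("expression values must be nonnegative")
  missing <- setdiff(colnames(values), names(condition_of))
  if (length(missing) > 0) {
    stop("sample(s) without a condition: ", paste(missing, collapse = ", "))
  }
  condition_of <- condition_of[colnames(values)]
  structure(
    list(values = values, condition_of = condition_of, unit = unit),
    class = "expr_matrix"
  )
}

#' Read an expression atlas (gene x cell category)
#'
#' @param path TSV with a `gene_id` column followed by one column per category.
#' @return Numeric matrix, rownames = gene ids, colnames = categories.
#' @export
read_atlas <- function(path) {
  tab <- read_table_schema(path, required = "gene_id")
  cats <- setdiff(names(tab), "gene_id")
  tab <- read_table_schema(path, required = "gene_id", numeric_cols = cats)
  m <- as.matrix(tab[cats])
  rownames(m) <- tab$gene_id
  m
}

#' Write a tibble as TSV (deterministic, no quoting surprises)
#' @param x Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
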