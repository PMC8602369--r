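#' Read a BED / narrowPeak file
#'
#' Accepts BED3, BED6 and the 10-column narrowPeak dialect. Coordinates are
#' kept 0-based half-open as in the file; 1-based or inverted coordinates are
#' rejected loudly rather than silently shifted. For narrowPeak input, column
#' 8 (-log10 p-value) is converted to a `p_value` column (`10^-col8`); a
#' narrowPeak value of -1 (p not available) yields `NA`.
#'
#' @param path file path; lines starting with `#`, `track` or `browser` are
#'   skipped.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name`, `score`, `strand`, `p_value`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), integer(), integer())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated columns")
  ncol_use <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  start <- suppressWarnings(as.integer(mat[, 2]))
  end <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", lineno[bad[1]], ": start >= end (coordinates must be ",
         "0-based half-open)")
  df <- data.frame(chrom = mat[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol_use >= 4L) df$name <- mat[, 4]
  if (ncol_use >= 5L) df$score <- suppressWarnings(as.numeric(mat[, 5]))
  if (ncol_use >= 6L) df$strand <- mat[, 6]
  if (ncol_use >= 10L) {                 # narrowPeak: col8 = -log10 p
    mlp <- suppressWarnings(as.numeric(mat[, 8]))
    df$p_value <- ifelse(is.na(mlp) | mlp < 0, NA_real_, 10^(-mlp))
  }
  validate_intervals(df, basename(path))
  df
}

#' Read a TSS table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `tss`, `strand`
#' (TSS is a single 0-based position). An optional `promoter_id` column
#' allows a gene to own several alternative promoters.
#'
#' @param path file path.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("TSS table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$tss < 0)) stop("TSS table: negative tss position")
  df$tss <- as.integer(df$tss)
  df
}

#' Read a differential-expression table
#'
#' Tab-separated with header columns `gene_id`, `log2fc`, `padj`.
#'
#' @param path file path.
#' @return data.frame with one row per gene.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Read a fragment-count table
#'
#' Long format, tab-separated with header columns `region_id`, `condition`,
#' `replicate`, `library` (one of `input`/`starr`) and `count`.
#'
#' @param path file path.
#' @return data.frame of counts.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "condition", "replicate", "library", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("count table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(df$library %in% c("input", "starr")))
    stop("count table: library must be 'input' or 'starr'")
  if (any(df$count < 0)) stop("count table: negative counts")
  df
}

#' Read a two-column chrom.sizes file
#'
#' @param path file path (chrom, length; no header).
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes needs two columns")
  sizes <- as.integer(df[[2]])
  if (any(is.na(sizes)) || any(sizes <= 0)) stop("chrom.sizes: invalid length")
  stats::setNames(sizes, as.character(df[[1]]))
}

#' Write a record table as TSV
#'
#' Plain tab-separated output with header; round-trips through
#' [utils::read.delim()] field-for-field, so every emitted table is a valid
#' input for downstream stages.
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Optional `name`, `score`, `strand` columns are emitted as BED6. When a
#' `p_value` column is present the 10-column narrowPeak dialect is written
#' instead, with column 8 carrying `-log10(p)`, so [read_bed()] round-trips
#' the p-values.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if (!is.null(intervals$p_value)) {
    out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                      name = if (is.null(intervals$name)) "." else intervals$name,
                      score = 0L,
                      strand = if (is.null(intervals$strand)) "." else intervals$strand,
                      signal = 0,
                      neglog10p = ifelse(is.na(intervals$p_value), -1,
                                         round(-log10(intervals$p_value), 6)),
                      qvalue = -1, peak = -1)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  if (!is.null(intervals$name)) {
    intervals$score_out <- if (is.null(intervals$score)) 0 else intervals$score
    intervals$strand_out <- if (is.null(intervals$strand)) "." else intervals$strand
    out <- intervals[, c(cols, "name", "score_out", "strand_out")]
  } else {
    out <- intervals[, cols, drop = FALSE]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
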