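#' Construct a table of genomic intervals
#'
#' Intervals are the universal region currency of the package: peaks, motif
#' sites, TADs, enhancers and promoter capture windows are all represented as
#' rows of a data.frame with 0-based half-open coordinates (BED convention).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, exclusive end; must satisfy `start < end`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @param ... further equal-length columns (e.g. `name`, `score`, `p_value`)
#'   carried along unchanged.
#'
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand` plus
#'   any extra columns, one row per interval.
#' @export
#' @examples
#' genomic_intervals("chr1", 0L, 100L)
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  strand <- rep_len(as.character(strand), length(chrom))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' @keywords internal
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stop(what, ": chrom must be non-empty")
  if (anyNA(df$start) || anyNA(df$end))
    stop(what, ": start/end must not be NA")
  if (any(df$start < 0L))
    stop(what, ": negative start (coordinates are 0-based half-open)")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, ": start >= end at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of +, -, .")
  invisible(df)
}

# 0-based half-open data.frame <-> 1-based closed GRanges
#' @keywords internal
.as_granges <- function(df) {
  validate_intervals(df)
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[s == "."] <- "*"
    s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra))
    S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

#' @keywords internal
.from_granges <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  s[s == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = s,
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc))
  rownames(df) <- NULL
  df
}

#' Merge overlapping intervals into a disjoint sorted set
#'
#' Two intervals are merged only when they share at least `min_overlap_bp`
#' bases; intervals that merely touch end-to-start (zero-base overlap in
#' half-open coordinates) are left separate.
#'
#' @param intervals interval data.frame (see [genomic_intervals()]).
#' @param min_overlap_bp minimum shared bases required to merge (default 1).
#' @return A data.frame of pairwise-disjoint intervals sorted by
#'   `(chrom, start)`; the union of covered bases equals that of the input.
#' @export
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(0L, 50L), c(100L, 150L)))
merge_intervals <- function(intervals, min_overlap_bp = 1L) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0L)
    return(genomic_intervals(character(), integer(), integer())[0, ])
  stopifnot(min_overlap_bp >= 1L)
  gr <- .as_granges(intervals[, c("chrom", "start", "end")])
  # min.gapwidth = 0 keeps touching intervals apart; larger required overlaps
  # map to negative gap widths, handled by shrinking then restoring.
  if (min_overlap_bp == 1L) {
    merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
  } else {
    hits <- GenomicRanges::findOverlaps(gr, gr,
                                        minoverlap = as.integer(min_overlap_bp))
    g <- .components(S4Vectors::queryHits(hits),
                     S4Vectors::subjectHits(hits), length(gr))
    merged <- unlist(BiocGenerics::range(S4Vectors::split(gr, g)),
                     use.names = FALSE)
  }
  out <- .from_granges(BiocGenerics::sort(merged))
  out$strand <- NULL
  out
}

# connected components via union-find (no graph dependency needed)
#' @keywords internal
.components <- function(from, to, n) {
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
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Intersect two interval sets
#'
#' Returns the base-pairwise overlap of the two sets: every output interval is
#' contained in at least one interval of each input and is at least 1 bp long.
#'
#' @param set_a,set_b interval data.frames.
#' @return data.frame of overlap intervals, sorted by `(chrom, start)`.
#' @export
intersect_intervals <- function(set_a, set_b) {
  validate_intervals(set_a, "set_a")
  validate_intervals(set_b, "set_b")
  empty <- genomic_intervals(character(), integer(), integer())[0, c("chrom", "start", "end")]
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(empty)
  ga <- .as_granges(set_a[, c("chrom", "start", "end")])
  gb <- .as_granges(set_b[, c("chrom", "start", "end")])
  # sets on disjoint chromosome universes legitimately intersect to empty;
  # silence the seqlevel-union notice GenomicRanges emits for that case
  out <- suppressWarnings(
    GenomicRanges::intersect(GenomicRanges::reduce(ga, min.gapwidth = 0L),
                             GenomicRanges::reduce(gb, min.gapwidth = 0L),
                             ignore.strand = TRUE))
  df <- .from_granges(BiocGenerics::sort(out))
  df$strand <- NULL
  df
}

#' Count intervals of one set overlapping each interval of another
#'
#' @param query interval data.frame whose rows are counted.
#' @param regions interval data.frame defining the windows.
#' @param min_overlap_bp minimum shared bases (default 1).
#' @return integer vector, one count per row of `regions`.
#' @export
count_overlaps <- function(query, regions, min_overlap_bp = 1L) {
  validate_intervals(regions, "regions")
  if (nrow(regions) == 0L) stop("regions must be non-empty")
  validate_intervals(query, "query")
  if (nrow(query) == 0L) return(integer(nrow(regions)))
  GenomicRanges::countOverlaps(
    .as_granges(regions[, c("chrom", "start", "end")]),
    .as_granges(query[, c("chrom", "start", "end")]),
    minoverlap = as.integer(min_overlap_bp), ignore.strand = TRUE)
}
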