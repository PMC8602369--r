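#' Promoter windows around TSS positions
#'
#' `capture_windows()` builds the strand-aware capture window
#' (-upstream/+downstream around the TSS); `flank_windows()` builds the
#' symmetric +/- flank window used for binding and proximity analyses.
#' Windows are clipped at position 0.
#'
#' @param tss TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`, optional
#'   `promoter_id`).
#' @param design a [promoter_design()].
#' @return interval data.frame with a `name` column (promoter id, falling
#'   back to gene id).
#' @export
capture_windows <- function(tss, design = promoter_design()) {
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$tss - design$upstream, tss$tss - design$downstream)
  end <- ifelse(plus, tss$tss + design$downstream, tss$tss + design$upstream)
  genomic_intervals(tss$chrom, pmax(0L, start), end, tss$strand,
                    name = if (is.null(tss$promoter_id)) tss$gene_id
                           else tss$promoter_id)
}

#' @rdname capture_windows
#' @param flank half-width in bp (default 1000).
#' @export
flank_windows <- function(tss, flank = 1000L) {
  genomic_intervals(tss$chrom, pmax(0L, tss$tss - as.integer(flank)),
                    tss$tss + as.integer(flank),
                    if (is.null(tss$strand)) "." else tss$strand,
                    name = if (is.null(tss$promoter_id)) tss$gene_id
                           else tss$promoter_id)
}

#' Composite peaks bound by every required TF
#'
#' Returns the maximal intervals covered by at least one peak of EVERY
#' input set (iterated pairwise intersection), e.g. composite ISGF3 peaks
#' from STAT1, STAT2 and IRF9 ChIP-seq peaks. Peaks are merged (>= 1 bp
#' overlap) within each TF first so stacked peaks are not double counted.
#'
#' @param peak_sets named list of interval data.frames, one per TF
#'   (at least 2).
#' @return interval data.frame of composite peaks (each >= 1 bp).
#' @export
composite_peaks <- function(peak_sets) {
  if (length(peak_sets) < 2L)
    stop("composite_peaks needs at least 2 peak sets")
  merged <- lapply(peak_sets, merge_intervals)
  Reduce(intersect_intervals, merged)
}

#' Categorize each induced gene by its nearest composite peak
#'
#' For each query gene, finds the nearest composite peak on the gene's
#' chromosome (edge distance from the TSS; 0 when the TSS lies inside a
#' peak; ties broken by leftmost peak) and assigns a positional category:
#' `same_promoter` when the peak is within `flank` of the gene's own TSS,
#' otherwise `another_promoter` when the peak lies within `flank` of any
#' other gene's TSS, otherwise `intergenic`. Genes with no peak on their
#' chromosome are reported as `unannotated` rather than forced into a
#' category.
#'
#' @param gene_tss TSS data.frame for the query genes.
#' @param peaks interval data.frame of composite peaks (non-empty).
#' @param all_tss TSS data.frame for all genes of the annotation (used for
#'   the `another_promoter` test; the query gene itself is excluded by
#'   `gene_id`).
#' @param flank promoter half-width in bp (default 1000, inclusive).
#' @return data.frame with `gene_id`, `distance`, `peak_chrom`,
#'   `peak_start`, `peak_end`, `category`.
#' @export
nearest_peak_category <- function(gene_tss, peaks, all_tss, flank = 1000L) {
  validate_intervals(peaks, "peaks")
  if (nrow(peaks) == 0L) stop("empty peak set")
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  res <- lapply(seq_len(nrow(gene_tss)), function(i) {
    g <- gene_tss[i, ]
    p <- peaks[peaks$chrom == g$chrom, ]
    if (nrow(p) == 0L)
      return(data.frame(gene_id = g$gene_id, distance = NA_integer_,
                        peak_chrom = NA_character_, peak_start = NA_integer_,
                        peak_end = NA_integer_, category = "unannotated",
                        stringsAsFactors = FALSE))
    d <- .edge_distance(g$tss, p$start, p$end)
    j <- which(d == min(d))[1]          # sorted by start -> leftmost tie
    category <- if (d[j] <= flank) "same_promoter" else {
      others <- all_tss[all_tss$chrom == g$chrom & all_tss$gene_id != g$gene_id, ]
      near_other <- nrow(others) > 0 &&
        any(.edge_distance_vec(others$tss, p$start[j], p$end[j]) <= flank)
      if (near_other) "another_promoter" else "intergenic"
    }
    data.frame(gene_id = g$gene_id, distance = d[j],
               peak_chrom = p$chrom[j], peak_start = p$start[j],
               peak_end = p$end[j], category = category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# distance from a point to interval edges; 0 inside (0-based half-open)
#' @keywords internal
.edge_distance <- function(pos, start, end) {
  pmax(0L, pmax(start - pos, pos - (end - 1L)))
}

# distances from many points to one interval
#' @keywords internal
.edge_distance_vec <- function(pos, start, end) {
  pmax(0L, pmax(start - pos, pos - (end - 1L)))
}

#' Promoter-by-TF binding matrix
#'
#' A promoter is bound by a TF when any peak of that TF overlaps the
#' promoter window by at least 1 bp.
#'
#' @param promoter_windows interval data.frame with `name` column (typically
#'   TSS +/- flank from [flank_windows()]).
#' @param peak_sets named list of interval data.frames, one per TF.
#' @return logical matrix, promoters x TFs, rownames from window names.
#' @export
binding_matrix <- function(promoter_windows, peak_sets) {
  stopifnot(length(peak_sets) >= 1L, !is.null(names(peak_sets)))
  m <- vapply(peak_sets, function(p) {
    if (nrow(p) == 0L) return(rep(FALSE, nrow(promoter_windows)))
    count_overlaps(p, promoter_windows) >= 1L
  }, logical(nrow(promoter_windows)))
  m <- matrix(m, nrow = nrow(promoter_windows),
              dimnames = list(promoter_windows$name, names(peak_sets)))
  m
}

#' TSS proximity of enhancer regions
#'
#' Distance from each enhancer midpoint to the nearest TSS; an enhancer is
#' `proximal` when the distance is at most `cut` (inclusive), `distal`
#' otherwise. Enhancers on chromosomes without any TSS get `NA` distance
#' and label.
#'
#' @param enhancers interval data.frame.
#' @param all_tss TSS data.frame (non-empty).
#' @param cut proximity cutoff in bp (default 1000).
#' @return data.frame with `distance` and `label` per enhancer.
#' @export
enhancer_tss_proximity <- function(enhancers, all_tss, cut = 1000L) {
  validate_intervals(enhancers, "enhancers")
  if (nrow(all_tss) == 0L) stop("empty TSS table")
  mid <- enhancers$start + (enhancers$end - enhancers$start) %/% 2L
  d <- vapply(seq_len(nrow(enhancers)), function(i) {
    t <- all_tss$tss[all_tss$chrom == enhancers$chrom[i]]
    if (length(t) == 0L) return(NA_integer_)
    min(abs(t - mid[i]))
  }, integer(1))
  data.frame(distance = d,
             label = ifelse(is.na(d), NA_character_,
                            ifelse(d <= cut, "proximal", "distal")),
             stringsAsFactors = FALSE)
}
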