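#' Nearest-neighbour TSS distances
#'
#' For each locus, the distance to the nearest other listed locus on the
#' same chromosome. Loci alone on their chromosome have no neighbour and
#' are excluded; their number is attached as attribute `n_excluded`.
#'
#' @param tss_list data.frame with `gene_id`, `chrom`, `tss`.
#' @return data.frame (`gene_id`, `chrom`, `distance`) with attribute
#'   `n_excluded`.
#' @export
nn_distances <- function(tss_list) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss_list)))
  parts <- split(tss_list, tss_list$chrom)
  usable <- parts[vapply(parts, nrow, integer(1)) >= 2L]
  n_excluded <- nrow(tss_list) - sum(vapply(usable, nrow, integer(1)))
  if (length(usable) == 0L)
    stop("need at least 2 loci on some chromosome")
  out <- do.call(rbind, lapply(usable, function(p) {
    ord <- order(p$tss)
    pos <- p$tss[ord]
    gaps <- diff(pos)
    d <- pmin(c(Inf, gaps), c(gaps, Inf))   # nearest neighbour on a line
    data.frame(gene_id = p$gene_id[ord], chrom = p$chrom[ord],
               distance = d, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Random gene control sample
#'
#' Uniform sample of `k` genes without replacement from a gene universe,
#' reproducible for a fixed seed.
#'
#' @param gene_universe TSS data.frame of candidate genes.
#' @param k sample size (`k <= nrow(gene_universe)`).
#' @param seed RNG seed.
#' @return data.frame of `k` sampled rows.
#' @export
random_gene_control <- function(gene_universe, k, seed = 1L) {
  if (k > nrow(gene_universe))
    stop("k exceeds the gene universe size")
  set.seed(seed)
  gene_universe[sample.int(nrow(gene_universe), k), , drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum difference of the two empirical CDFs,
#' evaluated over the pooled sample points; the two-sided p-value uses the
#' asymptotic Kolmogorov distribution with effective sample size
#' `n_a n_b / (n_a + n_b)`.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_test <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  d <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  list(statistic = d, p_value = 1 - .pkolmogorov(sqrt(n_eff) * d))
}

# Kolmogorov distribution P(K <= t), two-regime series evaluation:
# Jacobi theta form below t = 1 (fast convergence for small t), the
# alternating exponential series above
#' @keywords internal
.pkolmogorov <- function(t, tol = 1e-6) {
  if (t <= 0) return(0)
  if (t < 1) {
    z <- -(pi^2 / 8) / t^2
    k_max <- as.integer(sqrt(2 - log(tol)))
    k <- seq.int(1, by = 2, length.out = max(1, ceiling(k_max / 2)))
    k <- k[k < k_max]
    sqrt(2 * pi) * sum(exp(k^2 * z - log(t)))
  } else {
    z <- -2 * t^2
    s <- -1; k <- 1; old <- 0; new <- 1
    while (abs(old - new) > tol) {
      old <- new
      new <- new + 2 * s * exp(z * k^2)
      s <- -s; k <- k + 1
    }
    min(1, max(0, new))
  }
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (df = 1, upper-tail p). All
#' four marginals must be positive.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  stopifnot(identical(dim(m), c(2L, 2L)), all(m >= 0))
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in 2x2 table")
  expected <- outer(rs, cs) / n
  dev <- abs(m - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Shuffle-enrichment configuration
#'
#' @param n_shuffles number of random repositionings (default 100).
#' @param seed RNG seed.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @return list of class `enrichment_config`.
#' @export
enrichment_config <- function(n_shuffles = 100L, seed = 1L, chrom_sizes) {
  stopifnot(n_shuffles >= 2, !is.null(names(chrom_sizes)))
  structure(list(n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
                 chrom_sizes = chrom_sizes),
            class = "enrichment_config")
}

#' Region-shuffling overlap enrichment with a negative-binomial null
#'
#' The observed statistic is the number of query regions overlapping at
#' least one reference region by >= 1 bp. Each shuffle repositions every
#' query region uniformly within its own chromosome, preserving lengths and
#' counts, and the overlap count is recomputed. A negative binomial is
#' fitted to the shuffle counts by moments (`r = m^2 / (s^2 - m)`); when the
#' shuffle variance does not exceed the mean the null falls back to a
#' Poisson with the same mean (recorded in `method`). The p-value is the
#' upper tail `P(X >= observed)` under the fitted null.
#'
#' @param query_regions interval data.frame whose positions are randomized.
#' @param reference_regions interval data.frame held fixed.
#' @param config an [enrichment_config()]; `chrom_sizes` must cover every
#'   chromosome of `query_regions`.
#' @return list of class `enrichment_result`: `observed`, `shuffle_mean`,
#'   `shuffle_sd`, `nb_r`, `nb_p`, `p_value`, `method`, `shuffle_counts`.
#' @export
shuffle_enrichment <- function(query_regions, reference_regions, config) {
  stopifnot(inherits(config, "enrichment_config"))
  validate_intervals(query_regions, "query")
  validate_intervals(reference_regions, "reference")
  sizes <- config$chrom_sizes
  missing <- setdiff(query_regions$chrom, names(sizes))
  if (length(missing))
    stop("chrom_sizes lacks: ", paste(missing, collapse = ", "))
  len <- query_regions$end - query_regions$start
  room <- sizes[query_regions$chrom] - len
  if (any(room < 0))
    stop("query region longer than its chromosome")
  # merged references per chromosome allow a binary-search overlap test:
  # a query [s,e) hits some reference iff the rightmost reference starting
  # before e extends past s
  ref <- merge_intervals(reference_regions)
  ref_by_chr <- split(ref[, c("start", "end")], ref$chrom)
  chr_idx <- match(query_regions$chrom, names(ref_by_chr))
  overlap_count <- function(qstart, qend) {
    hits <- 0L
    for (ci in unique(chr_idx[!is.na(chr_idx)])) {
      sel <- which(chr_idx == ci)
      rr <- ref_by_chr[[ci]]
      j <- findInterval(qend[sel] - 0.5, rr$start)
      hits <- hits + sum(j > 0 & rr$end[pmax(j, 1L)] > qstart[sel])
    }
    hits
  }
  observed <- overlap_count(query_regions$start, query_regions$end)
  set.seed(config$seed)
  shuffle_counts <- vapply(seq_len(config$n_shuffles), function(i) {
    s <- floor(stats::runif(nrow(query_regions)) * (room + 1))
    overlap_count(s, s + len)
  }, numeric(1))
  m <- mean(shuffle_counts)
  s2 <- stats::var(shuffle_counts)
  if (is.finite(s2) && s2 > m && m > 0) {
    r <- m^2 / (s2 - m)
    p_val <- stats::pnbinom(observed - 1, size = r, mu = m, lower.tail = FALSE)
    method <- "negative binomial (moments)"
    nb_p <- r / (r + m)
  } else {
    r <- NA_real_; nb_p <- NA_real_
    p_val <- stats::ppois(observed - 1, lambda = m, lower.tail = FALSE)
    method <- "poisson fallback"
  }
  structure(list(observed = observed, shuffle_mean = m,
                 shuffle_sd = sqrt(max(s2, 0)), nb_r = r, nb_p = nb_p,
                 p_value = max(p_val, .Machine$double.xmin),
                 method = method, shuffle_counts = shuffle_counts),
            class = "enrichment_result")
}
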