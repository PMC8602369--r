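# Brute-force oracles, independent of the interval machinery under test.

# every covered base as "chrom:pos" strings
covered_bases <- function(df) {
  if (nrow(df) == 0L) return(character())
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L))))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000L,
                             max_len = 150L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

# quadratic overlap test between two interval tables
overlaps_pair <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

brute_count_overlaps <- function(query, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(vapply(seq_len(nrow(query)), function(j) {
      query$chrom[j] == regions$chrom[i] &&
        query$start[j] < regions$end[i] && regions$start[i] < query$end[j]
    }, logical(1)))
  }, integer(1))
}

# transitive-closure clustering oracle on (chrom, tss) records
brute_clusters <- function(chrom, tss, max_gap) {
  n <- length(tss)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(tss[i] - tss[j]) <= max_gap)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# small default genome for pipeline-level tests (fast but structured)
small_sim_config <- function(seed = 0L) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 2.5e7, n_genes = 400L,
             n_clusters = 10L)
}

run_fixture_pipeline <- function(dir, cfg) {
  rc <- run_config(
    counts = file.path(dir, "counts.tsv"), tss = file.path(dir, "tss.tsv"),
    de = file.path(dir, "de.tsv"),
    tf_peaks = stats::setNames(
      file.path(dir, paste0("peaks_", cfg$tf_names, ".bed")), cfg$tf_names),
    isre_sites = file.path(dir, "isre_sites.bed"),
    tads = file.path(dir, "tads.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    out_dir = file.path(dir, "out"))
  run_all(rc, quiet = TRUE)
}

# membership Jaccard of each planted cluster against its best recovered match
cluster_jaccards <- function(clustering, truth_clusters) {
  memb <- clustering$members
  rec <- split(memb$gene_id[!is.na(memb$cluster_id)],
               memb$cluster_id[!is.na(memb$cluster_id)])
  vapply(strsplit(truth_clusters$members, ","), function(t)
    max(vapply(rec, function(r) {
      r <- unique(r)
      length(intersect(t, r)) / length(union(t, r))
    }, numeric(1))), numeric(1))
}
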