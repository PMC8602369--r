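test_that("fixture sets are byte-identical across runs of the same seed", {
  cfg <- small_sim_config(seed = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_fixture_set(d1, cfg)
  simulate_fixture_set(d2, cfg)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # a different seed changes the draws
  d3 <- withr::local_tempdir()
  simulate_fixture_set(d3, small_sim_config(seed = 4L))
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})

test_that("planted clusters respect the span and isolation geometry", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  genes <- g$truth$genes
  tssmap <- g$tss[match(genes$gene_id, g$tss$gene_id), ]
  for (ci in unique(stats::na.omit(genes$cluster_id))) {
    pos <- tssmap$tss[which(genes$cluster_id %in% ci)]
    expect_lte(max(pos) - min(pos), cfg$cluster_span)
  }
  # induced loci of different clusters never sit within linkage range
  anchors <- do.call(rbind, lapply(unique(stats::na.omit(genes$cluster_id)),
    function(ci) {
      pos <- tssmap$tss[which(genes$cluster_id %in% ci)]
      data.frame(chrom = tssmap$chrom[which(genes$cluster_id %in% ci)][1],
                 lo = min(pos), hi = max(pos))
    }))
  for (chr in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == chr, ]
    a <- a[order(a$lo), ]
    if (nrow(a) > 1) expect_true(all(a$lo[-1] - a$hi[-nrow(a)] > 100000))
  }
})

test_that("count noise centers on the planted fold-changes", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  counts <- simulate_starr_counts(g, cfg)
  p <- g$truth$promoters
  # raw-count fold-changes (before library-size normalization, which
  # legitimately rescales all values by the library composition)
  wide <- split(counts$count, paste(counts$library, counts$condition,
                                    counts$replicate))
  inp <- wide[["input ns 1"]]
  bg <- !p$is_epromoter
  expect_equal(mean(wide[["starr ns 1"]][bg] / inp[bg]), 1, tolerance = 0.05)
  expect_equal(mean(wide[["starr stim 1"]][bg] / inp[bg]), 1, tolerance = 0.05)
  ind <- p$is_induced_epromoter
  expect_equal(mean(wide[["starr stim 1"]][ind] / wide[["starr ns 1"]][ind]),
               cfg$induction_ratio_planted,
               tolerance = 0.15 * cfg$induction_ratio_planted)
  # after normalization, induced Epromoters still stand out from background
  # by about the planted ratio
  act <- quantify_activity(counts, capture_windows(g$tss))
  ai <- match(p$promoter_id, act$promoter_id)
  rel <- mean(act$induction_ratio[ai][ind], na.rm = TRUE) /
    stats::median(act$induction_ratio[ai][bg], na.rm = TRUE)
  expect_equal(rel, cfg$induction_ratio_planted,
               tolerance = 0.15 * cfg$induction_ratio_planted)
})

test_that("zero dispersion gives deterministic counts equal to their means", {
  cfg <- small_sim_config()
  cfg$nb_dispersion <- 0
  g <- simulate_genome(cfg)
  counts <- simulate_starr_counts(g, cfg)
  inp <- counts[counts$library == "input", ]
  expect_true(all(inp$count == cfg$mu_input))
  c1 <- simulate_starr_counts(g, cfg)
  expect_identical(counts, c1)
  bg_id <- g$truth$promoters$promoter_id[!g$truth$promoters$is_epromoter]
  st <- counts[counts$library == "starr" & counts$region_id %in% bg_id, ]
  expect_true(all(st$count == cfg$mu_input))
})

test_that("the DE table reproduces the planted gene classes exactly", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  de <- simulate_de_table(g, cfg)
  cls <- classify_de(de)
  expect_equal(cls$de_class[match(g$truth$genes$gene_id, cls$gene_id)],
               g$truth$genes$de_class)
  # shuffling gene ids breaks the correspondence down to chance
  de_shuffled <- de
  set.seed(8)
  de_shuffled$gene_id <- sample(de_shuffled$gene_id)
  cls2 <- classify_de(de_shuffled)
  agree <- mean(cls2$de_class[match(g$truth$genes$gene_id, cls2$gene_id)] ==
                  g$truth$genes$de_class)
  expect_lt(agree, 1)
})

test_that("certain TF peaks at hubs make every Epromoter cluster detectable", {
  cfg <- small_sim_config()
  cfg$tf_peak_at_hub_prob <- 1
  g <- simulate_genome(cfg)
  tracks <- simulate_tf_tracks(g, cfg)
  bmat <- binding_matrix(flank_windows(g$tss, 1000L), tracks$peaks)
  rownames(bmat) <- g$tss$promoter_id
  genes <- g$truth$genes
  for (i in seq_len(nrow(g$truth$clusters))) {
    cl <- g$truth$clusters[i, ]
    member_genes <- strsplit(cl$members, ",")[[1]]
    proms <- g$tss$promoter_id[g$tss$gene_id %in% member_genes]
    expect_equal(predict_epromoter_like(proms, bmat),
                 cl$epromoter_like_truth, info = paste("cluster", i))
  }
})

test_that("without planted clusters, induced-gene spacing looks uniform", {
  cfg <- small_sim_config()
  cfg$n_clusters <- 0L
  g <- simulate_genome(cfg)
  genes <- g$truth$genes
  ind <- genes[genes$de_class == "induced", ]
  ind_tss <- g$tss[match(ind$gene_id, g$tss$gene_id), ]
  d_ind <- nn_distances(ind_tss)$distance
  set.seed(9)
  rand <- g$tss[sample.int(nrow(g$tss), nrow(ind_tss)), ]
  rand$gene_id <- paste0("r", seq_len(nrow(rand)))
  d_rand <- nn_distances(rand)$distance
  expect_gt(ks_test(d_ind, d_rand)$p_value, 0.01)
})
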