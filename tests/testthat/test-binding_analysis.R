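test_that("composite peaks require coverage by every TF set", {
  sets <- list(A = genomic_intervals("chr1", 0L, 100L),
               B = genomic_intervals("chr1", 50L, 150L),
               C = genomic_intervals("chr1", 90L, 200L))
  comp <- composite_peaks(sets)
  expect_equal(comp[, c("start", "end")], data.frame(start = 90L, end = 100L))

  sets$C <- genomic_intervals("chr2", 0L, 10L)     # one TF absent at the locus
  expect_equal(nrow(composite_peaks(sets)), 0L)
  expect_error(composite_peaks(list(genomic_intervals("chr1", 0L, 1L))),
               "at least 2")
})

test_that("composite peaks equal the per-base AND oracle and associate", {
  set.seed(41)
  for (rep in 1:5) {
    a <- random_intervals(40); b <- random_intervals(40); c <- random_intervals(40)
    comp <- composite_peaks(list(a = a, b = b, c = c))
    oracle <- Reduce(intersect, lapply(list(a, b, c), covered_bases))
    expect_setequal(covered_bases(comp), oracle)
    nested <- composite_peaks(list(ab = composite_peaks(list(a = a, b = b)),
                                   c = c))
    expect_setequal(covered_bases(nested), covered_bases(comp))
  }
})

test_that("nearest-peak categories follow the positional rules", {
  all_tss <- data.frame(gene_id = c("g1", "g2", "g3"),
                        chrom = "chr1",
                        tss = c(10000L, 60300L, 500000L),
                        strand = "+")
  peaks <- genomic_intervals("chr1", c(9900L, 60000L, 300000L),
                             c(10100L, 60200L, 300400L))
  ann <- nearest_peak_category(all_tss, peaks, all_tss, flank = 1000L)
  expect_equal(ann$category[1], "same_promoter")      # TSS inside peak
  expect_equal(ann$distance[1], 0L)
  # g3: nearest peak 199.6 kb away but within 1 kb of no one -> intergenic
  expect_equal(ann$category[3], "intergenic")
  # a gene far from its own nearest peak which sits at another promoter
  far <- data.frame(gene_id = "g4", chrom = "chr1", tss = 110000L, strand = "+")
  ann4 <- nearest_peak_category(far, peaks, all_tss, flank = 1000L)
  expect_equal(ann4$category, "another_promoter")     # peak at g2's promoter
  expect_error(nearest_peak_category(all_tss, peaks[0, ], all_tss),
               "empty peak set")
})

test_that("genes without a peak on their chromosome are left unannotated", {
  g <- data.frame(gene_id = "g", chrom = "chrX", tss = 100L, strand = "+")
  ann <- nearest_peak_category(g, genomic_intervals("chr1", 0L, 10L), g)
  expect_equal(ann$category, "unannotated")
  expect_true(is.na(ann$distance))
})

test_that("nearest-peak distances agree with the all-pairs oracle", {
  set.seed(42)
  tss <- data.frame(gene_id = paste0("g", 1:200),
                    chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    tss = sample.int(500000L, 200), strand = "+")
  st <- sample.int(500000L, 80)
  peaks <- genomic_intervals(sample(c("chr1", "chr2"), 80, TRUE), st, st + 200L)
  ann <- nearest_peak_category(tss, peaks, tss)
  for (i in seq_len(50)) {          # spot-check a subset exhaustively
    p <- peaks[peaks$chrom == tss$chrom[i], ]
    d <- pmax(0L, pmax(p$start - tss$tss[i], tss$tss[i] - (p$end - 1L)))
    expect_equal(ann$distance[i], min(d))
  }
})

test_that("binding matrix marks >=1 bp overlaps only", {
  w <- genomic_intervals("chr1", 0L, 2000L, name = "p1")
  sets <- list(TF1 = genomic_intervals("chr1", 999L, 1100L),
               TF2 = genomic_intervals("chr1", 2000L, 2100L))
  m <- binding_matrix(w, sets)
  expect_true(m["p1", "TF1"])
  expect_false(m["p1", "TF2"])      # half-open: touching is not overlap

  set.seed(43)
  wins <- random_intervals(30)
  wins$name <- paste0("p", seq_len(30))
  sets <- list(X = random_intervals(40), Y = random_intervals(40))
  m <- binding_matrix(wins, sets)
  expect_equal(unname(m[, "X"]), brute_count_overlaps(sets$X, wins) >= 1)
  expect_equal(unname(m[, "Y"]), brute_count_overlaps(sets$Y, wins) >= 1)
})

test_that("enhancer TSS proximity is midpoint-based and inclusive at the cut", {
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    tss = c(5000L, 100000L), strand = "+")
  enh <- genomic_intervals("chr1", c(4900L, 5900L, 20000L),
                           c(5100L, 6100L, 20200L))
  prox <- enhancer_tss_proximity(enh, tss, cut = 1000L)
  expect_equal(prox$distance, c(0L, 1000L, 15100L))
  expect_equal(prox$label, c("proximal", "proximal", "distal"))
  expect_error(enhancer_tss_proximity(enh, tss[0, ]), "empty TSS")
})
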