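test_that("fragments extend from the 5' end in the read direction", {
  plus <- extend_fragments(genomic_intervals("chr1", 1000L, 1050L, "+"), 314L)
  expect_equal(c(plus$start, plus$end), c(1000L, 1314L))
  minus <- extend_fragments(genomic_intervals("chr1", 1000L, 1050L, "-"), 314L)
  expect_equal(c(minus$start, minus$end), c(736L, 1050L))
  clipped <- extend_fragments(genomic_intervals("chr1", 100L, 150L, "-"), 314L)
  expect_equal(c(clipped$start, clipped$end), c(0L, 150L))
  expect_error(extend_fragments(genomic_intervals("chr1", 0L, 50L, ".")),
               "strand")
})

test_that("region coverage counts >=1 bp overlaps, matching brute force", {
  frag <- genomic_intervals("chr1", 0L, 314L, "+")
  expect_equal(region_coverage(frag, genomic_intervals("chr1", 250L, 500L)), 1L)
  expect_equal(region_coverage(genomic_intervals("chr1", 0L, 100L, "+"),
                               genomic_intervals("chr1", 100L, 200L)), 0L)
  set.seed(21)
  frags <- random_intervals(500)
  frags$strand <- "+"
  regions <- random_intervals(20)
  expect_equal(region_coverage(frags, regions),
               brute_count_overlaps(frags, regions))
})

test_that("fpkm normalizes by region length and library size", {
  expect_equal(fpkm(10, 250, 1e6), 40)
  expect_equal(fpkm(0, 250, 1e6), 0)
  expect_error(fpkm(1, 250, 0), "total_fragments")
  set.seed(22)
  for (i in 1:20) {
    count <- sample.int(1000, 1); len <- sample.int(5000, 1)
    tot <- sample.int(1e7, 1)
    expect_equal(fpkm(2 * count, len, 2 * tot), fpkm(count, len, tot))
    expect_gt(fpkm(2 * count, len, tot), fpkm(count, len, tot))
  }
})

test_that("input FPKM floor removes promoters before fold-change", {
  r <- activity_fold_change(c(8, 3, 2), c(2, 0.5, 2), 1)
  expect_equal(r$fold_change, c(4, NA, 1))
  expect_equal(r$removed, c(FALSE, TRUE, FALSE))
})

test_that("inflection threshold finds the knee of the ranked log2 curve", {
  # piecewise curve: flat head then log-linear decay; knee at the breakpoint
  fc <- c(rep(8, 20), 2^seq(log2(1.5), log2(0.5), length.out = 180))
  tau <- inflection_threshold(fc)
  # independent oracle: exhaustive max-distance search over all ranks
  s <- sort(fc, decreasing = TRUE); y <- log2(s); n <- length(y)
  d <- vapply(seq_len(n), function(i) {
    abs((y[n] - y[1]) * i - (n - 1) * y[i] + (n - 1) * y[1] - (y[n] - y[1])) /
      sqrt((n - 1)^2 + (y[n] - y[1])^2)
  }, numeric(1))
  expect_equal(tau, s[which.max(d)])
  expect_equal(tau, 1.5)            # top of the decay segment at the corner

  expect_error(inflection_threshold(2^seq(4, 0, length.out = 50)),
               "degenerate")
  expect_error(inflection_threshold(c(2, 2, 2)), "degenerate")
  expect_error(inflection_threshold(c(1, 2)), "degenerate")

  set.seed(23)
  for (i in 1:10) {                 # scale equivariance
    fc <- 2^c(rnorm(30, 3), rnorm(200, 0))
    cc <- runif(1, 0.1, 10)
    expect_equal(inflection_threshold(fc * cc), inflection_threshold(fc) * cc,
                 tolerance = 1e-12)
  }
})

test_that("activity calls are inclusive at tau, induction strict at the ratio", {
  calls <- call_epromoters(matrix(c(2, 2, 1, 1, 4, 0), 3, 2, byrow = TRUE), 2)
  expect_equal(unname(calls$epromoter), c(TRUE, FALSE, TRUE))  # mean 2, 1, 2
  expect_equal(unname(calls$active[1, ]), c(TRUE, TRUE))

  ir <- call_induced_repressed(
    fc_stim = matrix(c(2.5 * 1, 1.8 * 1,   2, 2,   0.3, 0.4), 3, 2, byrow = TRUE),
    fc_ns = matrix(1, 3, 2),
    active_stim = matrix(c(TRUE, FALSE), 3, 2, byrow = TRUE),
    active_ns = matrix(TRUE, 3, 2))
  expect_equal(ir$induction_ratio, c(2.15, 2, 0.35))
  expect_true(ir$induced[1])
  expect_false(ir$induced[2])       # mean ratio exactly 2 is not induced
  expect_true(ir$repressed[3])      # mirrored rule, below 1/2
})

test_that("zero non-stimulated fold-change uses the pseudo floor", {
  ir <- call_induced_repressed(matrix(0.05, 1, 1), matrix(0, 1, 1),
                               matrix(TRUE, 1, 1), matrix(FALSE, 1, 1),
                               pseudo_fc = 0.01)
  expect_equal(ir$induction_ratio, 5)
})

test_that("planted induced Epromoters are recovered from simulated counts", {
  cfg <- small_sim_config()
  g <- simulate_genome(cfg)
  counts <- simulate_starr_counts(g, cfg)
  act <- quantify_activity(counts, capture_windows(g$tss))
  truth <- g$truth$promoters[match(act$promoter_id,
                                   g$truth$promoters$promoter_id), ]
  tp <- sum(act$induced_epromoter & truth$is_induced_epromoter)
  expect_gte(tp / sum(act$induced_epromoter), 0.9)
  expect_gte(tp / sum(truth$is_induced_epromoter), 0.9)
  # thresholds sit between the background bulk and the planted actives
  expect_true(all(attr(act, "tau") > 0.5 & attr(act, "tau") < 5))
})
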