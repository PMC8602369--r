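test_that("nearest-neighbour distances match the all-pairs oracle", {
  tss <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                    tss = c(0L, 100L, 500L))
  d <- nn_distances(tss)
  expect_equal(d$distance[match(c("a", "b", "c"), d$gene_id)],
               c(100, 100, 400))

  lone <- rbind(tss, data.frame(gene_id = "x", chrom = "chrX", tss = 7L))
  d2 <- nn_distances(lone)
  expect_false("x" %in% d2$gene_id)
  expect_equal(attr(d2, "n_excluded"), 1L)
  expect_error(nn_distances(lone[4, ]), "at least 2")

  set.seed(71)
  big <- data.frame(gene_id = paste0("g", 1:200),
                    chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    tss = sample.int(1e6, 200))
  d3 <- nn_distances(big)
  for (i in sample.int(200, 30)) {
    same <- big[big$chrom == big$chrom[i] & big$gene_id != big$gene_id[i], ]
    expect_equal(d3$distance[d3$gene_id == big$gene_id[i]],
                 min(abs(same$tss - big$tss[i])))
  }
})

test_that("random gene control is a reproducible uniform subsample", {
  universe <- data.frame(gene_id = paste0("g", 1:50), chrom = "chr1",
                         tss = seq_len(50) * 1000L)
  s1 <- random_gene_control(universe, 10, seed = 99)
  s2 <- random_gene_control(universe, 10, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10L)
  all50 <- random_gene_control(universe, 50, seed = 1)
  expect_setequal(all50$gene_id, universe$gene_id)
  expect_error(random_gene_control(universe, 51, seed = 1), "exceeds")
})

test_that("KS statistic follows the explicit ECDF enumeration", {
  same <- ks_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3); b <- c(1, 2, 3, 1000)
  # hand ECDF: at x = 3, F_a = 1, F_b = 3/4; sup difference = 1/4
  r <- ks_test(a, b)
  expect_equal(r$statistic, 0.25)
})

test_that("KS agrees with the reference implementation to 1e-8", {
  set.seed(72)
  for (i in 1:100) {
    a <- rnorm(sample(5:150, 1))
    b <- rnorm(sample(5:150, 1), sd = runif(1, 0.5, 2))
    mine <- ks_test(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("2x2 chi-square equals the expected-counts and closed forms", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # conserved-ISG contingency: 22/16 vs 47/347, hand sum((O-E)^2/E)
  m <- matrix(c(22, 47, 16, 347), 2, 2)
  r <- chi_square_2x2(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$statistic, sum((m - E)^2 / E))
  # closed form (ad - bc)^2 N / (r1 r2 c1 c2)
  expect_equal(r$statistic,
               (22 * 347 - 16 * 47)^2 * sum(m) /
                 prod(c(rowSums(m), colSums(m))), tolerance = 1e-12)
  ref <- stats::chisq.test(m, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)
  expect_lt(r$p_value, 1e-4)

  expect_equal(chi_square_2x2(m[2:1, ])$statistic, r$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "zero marginal")
  yates <- chi_square_2x2(m, correct = TRUE)
  expect_equal(yates$statistic,
               unname(stats::chisq.test(m, correct = TRUE)$statistic))
})

test_that("shuffle enrichment is deterministic and detects true overlap", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  set.seed(73)
  st <- as.integer(runif(30, 0, 1e6 - 300))
  ref <- genomic_intervals(sample(names(sizes), 30, TRUE), st, st + 300L)
  cfg <- enrichment_config(n_shuffles = 50, seed = 7, chrom_sizes = sizes)
  e1 <- shuffle_enrichment(ref, ref, cfg)
  e2 <- shuffle_enrichment(ref, ref, cfg)
  expect_identical(e1, e2)                      # fixed seed, bit-identical
  expect_equal(e1$observed, 30L)                # query == reference
  expect_lt(e1$p_value, 0.01)
  expect_gte(e1$p_value, .Machine$double.xmin)

  expect_error(shuffle_enrichment(
    genomic_intervals("chr1", 0L, 2e6), ref, cfg), "longer than")
  expect_error(shuffle_enrichment(
    genomic_intervals("chr9", 0L, 10L), ref, cfg), "chrom_sizes lacks")
})

test_that("degenerate shuffle counts fall back to a Poisson null", {
  sizes <- c(chr1 = 1000)
  ref <- genomic_intervals("chr1", 0L, 1000L)    # covers the chromosome
  q <- genomic_intervals("chr1", c(0L, 500L), c(100L, 600L))
  e <- shuffle_enrichment(q, ref, enrichment_config(2, seed = 1, sizes))
  expect_equal(e$method, "poisson fallback")     # all shuffles count 2
  expect_equal(e$shuffle_sd, 0)
  expect_true(e$p_value > 0 && e$p_value <= 1)
})

test_that("an observed count at the shuffle mean is not significant", {
  # NB tail at the mean is ~0.5 up to discreteness
  sizes <- c(chr1 = 1e5)
  set.seed(74)
  st <- as.integer(runif(40, 0, 1e5 - 200))
  ref <- genomic_intervals(rep("chr1", 40), st, st + 200L)
  qs <- as.integer(runif(25, 0, 1e5 - 150))
  q <- genomic_intervals(rep("chr1", 25), qs, qs + 150L)
  e <- shuffle_enrichment(q, ref, enrichment_config(100, seed = 5, sizes))
  p_at_mean <- if (e$method == "negative binomial (moments)") {
    stats::pnbinom(round(e$shuffle_mean) - 1, size = e$nb_r,
                   mu = e$shuffle_mean, lower.tail = FALSE)
  } else {
    stats::ppois(round(e$shuffle_mean) - 1, e$shuffle_mean, lower.tail = FALSE)
  }
  expect_gt(p_at_mean, 0.3)
  expect_lt(p_at_mean, 0.7)
})
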