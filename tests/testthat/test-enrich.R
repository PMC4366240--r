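test_that("TSS-bin counting honours the half-open strand-aware window", {
  gm <- toy_genome()   # gA + strand TSS 100000; gB - strand TSS 300000
  reads <- list(
    c_chip_rep1 = c(99950, 99949, 101499, 101500,       # gA edges
                    300050, 300051, 298501, 298500))    # gB edges
  bt <- count_bin_reads(reads, gm, samples = chip_samples(n_chip = 1,
                                                          n_input = 0))
  # + strand: [TSS-50, TSS+1500) -> 99950 in, 99949 out, 101499 in, 101500 out
  expect_equal(unname(bt$counts["gA", 1]), 2L)
  # - strand mirror: (TSS-1500, TSS+50] -> 300050 in, 300051 out, 298501 in
  expect_equal(unname(bt$counts["gB", 1]), 2L)
  expect_error(count_bin_reads(list(c_chip_rep1 = 2e6), gm,
                               samples = chip_samples(n_chip = 1,
                                                      n_input = 0)),
               "outside")
})

test_that("strand mirror of gene and reads preserves the bin count", {
  gm <- toy_genome()
  L <- unname(gm$chrom_sizes["chr1"])
  set.seed(413)
  pos <- 100000 + sample(-60:1560, 40)
  fwd <- count_bin_reads(list(c_chip_rep1 = pos), gm,
                         samples = chip_samples(n_chip = 1, n_input = 0))
  # reflect the genome and the reads about the chromosome
  g2 <- gm$genes
  g2$strand <- ifelse(g2$strand == "+", "-", "+")
  g2$tss <- L - 1 - g2$tss
  g2$tes <- L - 1 - g2$tes
  g2$exon_starts <- vapply(strsplit(gm$genes$exon_ends, ","), function(e)
    paste(rev(L - as.numeric(e)), collapse = ","), "")
  g2$exon_ends <- vapply(strsplit(gm$genes$exon_starts, ","), function(s)
    paste(rev(L - as.numeric(s)), collapse = ","), "")
  flip_gm <- genome_model(g2, gm$cgis, gm$chrom_sizes)
  rev_reads <- list(c_chip_rep1 = L - 1 - pos)
  bwd <- count_bin_reads(rev_reads, flip_gm,
                         samples = chip_samples(n_chip = 1, n_input = 0))
  expect_identical(unname(fwd$counts), unname(bwd$counts))
})

test_that("sample ids parse into annotations", {
  s <- p53targets:::parse_sample_ids(c("RIS_chip_rep2", "pApo_input_rep1"))
  expect_equal(s$role, c("chip", "input"))
  expect_equal(s$condition, c("RIS", "pApo"))
  expect_equal(s$replicate, c(2L, 1L))
  expect_error(p53targets:::parse_sample_ids("whatever"), "cannot parse")
})

test_that("count normalization equalises library sizes as specified", {
  cnt <- matrix(c(10, 30, 60, 20, 60, 120), 3, 2,
                dimnames = list(paste0("g", 1:3), NULL))
  bt <- bin_count_table(cnt, chip_samples(n_chip = 1, n_input = 1))
  lib <- normalize_counts(bt, method = "libsize")
  # totals 100 and 200 -> factors 2/3 and 4/3; column 2 halved vs column 1
  expect_equal(unname(colSums(lib$normalized)), c(150, 150))
  expect_equal(lib$normalized[, 1], lib$normalized[, 2])
  # identical columns unchanged under either method
  same <- bin_count_table(cbind(cnt[, 1], cnt[, 1]),
                          chip_samples(n_chip = 1, n_input = 1))
  expect_equal(normalize_counts(same, "libsize")$normalized[, 1],
               cnt[, 1] + 0, ignore_attr = TRUE)
  expect_equal(normalize_counts(same, "quantile")$normalized[, 2],
               cnt[, 1] + 0, ignore_attr = TRUE)
  zero <- bin_count_table(cbind(cnt[, 1], 0L),
                          chip_samples(n_chip = 1, n_input = 1))
  expect_error(normalize_counts(zero, "libsize"), "zero effective")
  # quantile factors ignore a heavily enriched tail
  set.seed(414)
  base <- rnbinom(500, mu = 20, size = 10)
  enriched <- base
  enriched[1:50] <- enriched[1:50] * 10
  bt2 <- bin_count_table(cbind(base, enriched),
                         chip_samples(n_chip = 1, n_input = 1))
  qf <- normalize_counts(bt2, "quantile")$factors
  lf <- normalize_counts(bt2, "libsize")$factors
  expect_lt(abs(qf[2] / qf[1] - 1), abs(lf[2] / lf[1] - 1))
})

test_that("dispersion estimate recovers the simulated phi", {
  set.seed(415)
  cnt <- cbind(matrix(rnbinom(3000 * 3, mu = 20, size = 10), 3000, 3),
               matrix(rnbinom(3000 * 3, mu = 20, size = 10), 3000, 3))
  phi <- estimate_dispersion(cnt, rep(c("chip", "input"), each = 3))
  expect_lt(abs(phi - 0.1) / 0.1, 0.35)
})

test_that("enrichment posterior behaves at the null, under strong signal,
           and in the prior limits", {
  set.seed(416)
  cnt <- matrix(rnbinom(300 * 6, mu = 20, size = 10), 300, 6,
                dimnames = list(paste0("g", 1:300), NULL))
  cnt[1, ] <- 20L                      # exactly equal chip and input
  cnt[2, ] <- c(rep(200L, 3), rep(20L, 3))  # 10x enrichment
  bt <- bin_count_table(cnt, chip_samples())
  set.seed(417)
  e <- enrichment_posterior(bt, pi = 0.5, phi = 0.1)
  expect_lte(e$pC[1], 0.5)
  expect_gt(e$pC[2], 0.95)
  expect_true(all(e$pC >= 0 & e$pC <= 1))
  # pi -> 0 forces posteriors toward 0 wherever the Bayes factor is finite
  # (a decisively enriched gene rightly survives any fixed prior)
  null_bt <- bin_count_table(cnt[-2, ], chip_samples())
  set.seed(417)
  e0 <- enrichment_posterior(null_bt, pi = 1e-9, phi = 0.1)
  expect_lt(max(e0$pC), 1e-3)
  # all-zero rows return the prior, flagged
  cnt0 <- cnt; cnt0[3, ] <- 0L
  set.seed(417)
  ez <- enrichment_posterior(bin_count_table(cnt0, chip_samples()),
                             pi = 0.5, phi = 0.1)
  expect_true(ez$flagged[3])
  expect_equal(ez$pC[3], 0.5)
})

test_that("swapping chip and input labels inverts confident enrichment", {
  set.seed(418)
  cnt <- matrix(rnbinom(300 * 6, mu = 20, size = 10), 300, 6,
                dimnames = list(paste0("g", 1:300), NULL))
  enriched <- sample.int(300, 30)
  cnt[enriched, 1:3] <- matrix(rnbinom(30 * 3, mu = 100, size = 10), 30, 3)
  bt <- bin_count_table(cnt, chip_samples())
  set.seed(419)
  e1 <- enrichment_posterior(bt, pi = 0.5, phi = 0.1)
  swapped <- bin_count_table(cnt[, c(4:6, 1:3)], chip_samples())
  set.seed(419)
  e2 <- enrichment_posterior(swapped, pi = 0.5, phi = 0.1)
  up <- e1$pC > 0.5
  expect_true(all(e2$pC[up] <= 0.5))
})

test_that("the posterior is monotone in the chip/input ratio at fixed totals", {
  set.seed(420)
  cnt <- matrix(rnbinom(200 * 6, mu = 60, size = 10), 200, 6,
                dimnames = list(paste0("g", 1:200), NULL))
  for (i in 1:12) cnt[i, ] <- c(rep(10L * i, 3), rep(130L - 10L * i, 3))
  bt <- bin_count_table(cnt, chip_samples())
  set.seed(421)
  e <- enrichment_posterior(bt, pi = 0.5, phi = 0.1, norm = "libsize")
  expect_false(is.unsorted(e$pC[1:12]))
})

test_that("the empirical-Bayes model prior settles near the bound fraction", {
  cfg <- sim_config(seed = 122)
  g <- simulate_genome(cfg)
  tr <- plant_truth(g, cfg)
  ch <- simulate_chip(g, tr, cfg)
  set.seed(423)
  e <- enrichment_posterior(ch$counts, condition = "RIS")
  pi_hat <- attr(e, "pi")
  expect_gt(pi_hat, 0.05)
  expect_lt(pi_hat, 0.35)
  # the estimated prior must not cost sensitivity at bound genes
  expect_gt(mean(e$pC[tr$bound] > 0.9), 0.9)
})
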