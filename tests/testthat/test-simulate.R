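test_that("generators are fully deterministic given the seed", {
  cfg <- small_config(seed = 101)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(as.data.frame(g1$cgis), as.data.frame(g2$cgis))
  t1 <- plant_truth(g1, cfg)
  expect_identical(t1, plant_truth(g2, cfg))
  c1 <- simulate_chip(g1, t1, cfg)
  c2 <- simulate_chip(g1, t1, cfg)
  expect_identical(c1$counts$counts, c2$counts$counts)
  expect_identical(c1$reads, c2$reads)
  expect_identical(as.data.frame(c1$peaks), as.data.frame(c2$peaks))
  e1 <- simulate_expression(g1, t1, cfg)
  expect_identical(e1, simulate_expression(g1, t1, cfg))
  # and the generator does not disturb the caller's RNG stream
  set.seed(9); a <- runif(1)
  set.seed(9); invisible(simulate_genome(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("genome layout respects spacing, strands and CGI placement", {
  expect_error(simulate_genome(
    sim_config(n_genes = 100, chrom_length = 1e6, n_bound_genes = 10,
               n_responsive_genes = 10, n_target_genes = 5)),
    "120 kb")
  cfg0 <- small_config(seed = 102, cgi_promoter_fraction = 0)
  expect_length(simulate_genome(cfg0)$cgis, 0)
  cfg1 <- small_config(seed = 103, cgi_promoter_fraction = 1)
  g <- simulate_genome(cfg1)
  expect_length(g$cgis, 50)
  tss <- gi(g$genes$chrom, pmax(g$genes$tss - 500, 0), g$genes$tss + 500)
  expect_true(all(GenomicRanges::countOverlaps(tss, g$cgis) > 0))
  expect_setequal(unique(g$genes$strand), c("+", "-"))
})

test_that("planted truth hits the configured counts and the CGI bias", {
  cfg <- small_config(seed = 104)
  g <- simulate_genome(cfg)
  tr <- plant_truth(g, cfg)
  expect_equal(sum(tr$bound), cfg$n_bound_genes)
  expect_equal(sum(tr$responsive), cfg$n_responsive_genes)
  expect_equal(sum(tr$is_target), cfg$n_target_genes)
  expect_true(all((tr$direction == "none") == !tr$responsive))

  none <- plant_truth(g, small_config(seed = 104, n_bound_genes = 0,
                                      n_target_genes = 0))
  expect_equal(sum(none$bound), 0)
  expect_error(plant_truth(g, small_config(n_bound_genes = 40,
                                           n_responsive_genes = 40,
                                           n_target_genes = 5)),
               "exceed")

  # 3:1 CGI odds at cgi fraction 0.5: expected CGI share of targets ~ 0.75
  base <- sim_config(n_genes = 400, chrom_length = 400 * 125000,
                     n_bound_genes = 20, n_responsive_genes = 20,
                     n_target_genes = 20, seed = 1)
  gg <- simulate_genome(base)
  shares <- vapply(1:200, function(i) {
    tri <- plant_truth(gg, sim_config(n_genes = 400,
                                      chrom_length = 400 * 125000,
                                      n_bound_genes = 20,
                                      n_responsive_genes = 20,
                                      n_target_genes = 20, seed = 1000 + i))
    mean(tri$promoter_class[tri$is_target] == "CGI")
  }, 0)
  expect_lt(abs(mean(shares) - 0.75), 0.03)
})

test_that("ChIP counts have the configured NB background and null behaviour", {
  cfg <- sim_config(seed = 105)
  g <- simulate_genome(cfg)
  tr <- plant_truth(g, cfg)
  ch <- simulate_chip(g, tr, cfg)
  inp <- ch$counts$counts[, ch$counts$samples$role == "input", drop = FALSE]
  mu <- cfg$chip_mean_background
  # NB mean check: 3 standard errors across 2000 genes x replicates
  se <- sqrt((mu + cfg$nb_dispersion * mu^2) / length(inp))
  expect_lt(abs(mean(inp) - mu), 3 * se)

  # fold 1: chip and input counts are exchangeable (KS distance below the
  # alpha = 0.01 critical value for n = 2000 per sample)
  cfg0 <- sim_config(seed = 106, chip_fold_enrichment = 1)
  ch0 <- simulate_chip(g, tr, cfg0)
  chip0 <- ch0$counts$counts[, "RIS_chip_rep1"]
  inp0 <- ch0$counts$counts[, "RIS_input_rep1"]
  d <- suppressWarnings(ks.test(chip0, inp0)$statistic)
  expect_lt(unname(d), 1.628 * sqrt(2 / length(chip0)))
})

test_that("peak dropout and decoys behave at the boundaries", {
  cfg <- small_config(seed = 107, peak_dropout_prob = 1, decoy_frac = 0)
  g <- simulate_genome(cfg)
  tr <- plant_truth(g, cfg)
  expect_length(simulate_chip(g, tr, cfg)$peaks, 0)

  cfg2 <- small_config(seed = 108, peak_dropout_prob = 0, decoy_frac = 0.1)
  ch2 <- simulate_chip(g, tr, cfg2)
  pk <- ch2$peaks
  # every bound gene present in every replicate of every condition
  n_exp <- sum(tr$bound) * sum(cfg2$conditions)
  expect_equal(sum(GenomicRanges::countOverlaps(
    pk, gi(g$genes$chrom[tr$bound], g$genes$tss[tr$bound] - 1000,
           g$genes$tss[tr$bound] + 1000)) > 0), n_exp,
    tolerance = 0.02)
  # decoys: 10% of gene count per condition, each in exactly one replicate
  expect_equal(length(pk), n_exp + round(0.1 * cfg2$n_genes) *
                 length(cfg2$conditions))
})

test_that("recounting simulated reads reproduces the count table exactly", {
  cfg <- small_config(seed = 109)
  ds <- simulate_dataset(cfg)
  bt <- count_bin_reads(ds$chip$reads, ds$genome,
                        samples = ds$chip$counts$samples)
  expect_identical(bt$counts, ds$chip$counts$counts)
})

test_that("expression arms carry the planted shifts with the right sign", {
  cfg <- sim_config(seed = 110)
  g <- simulate_genome(cfg)
  tr <- plant_truth(g, cfg)
  ex <- simulate_expression(g, tr, cfg)
  expect_equal(ncol(ex$vector), 3)
  expect_equal(ncol(ex$shp53), 3)
  diffs <- rowMeans(ex$shp53) - rowMeans(ex$vector)
  ind <- tr$direction == "induced"
  rep <- tr$direction == "repressed"
  tol <- 3 * cfg$expr_sd / sqrt(cfg$n_expr_replicates)
  expect_lt(abs(mean(diffs[ind]) + cfg$expr_effect), tol)
  expect_lt(abs(mean(diffs[rep]) - cfg$expr_effect), tol)

  # effect 0: per-gene classical-t p-values are uniform (KS at alpha 0.01)
  cfg0 <- sim_config(seed = 111, expr_effect = 0)
  ex0 <- simulate_expression(g, tr, cfg0)
  m <- cbind(ex0$vector, ex0$shp53)
  fc <- fit_contrast(m, rep(c("vector", "shp53"), each = 3))
  mt <- moderated_t(fc$log2fc, fc$s2, 3, 3, fc$df[1])
  expect_gt(ks.test(mt$p, "punif")$p.value, 0.01)
})

test_that("a simulated dataset writes to plain-text files and reads back", {
  cfg <- small_config(seed = 112)
  ds <- simulate_dataset(cfg)
  out <- tempfile("simds")
  write_dataset(ds, out)
  genes <- read_gene_table(file.path(out, "genes.tsv"))
  expect_equal(genes$tss, ds$genome$genes$tss)
  cnt <- read_matrix_tsv(file.path(out, "counts.tsv"))
  expect_equal(unname(cnt), unname(ds$chip$counts$counts) + 0)
  expect_true(file.exists(file.path(out, "peaks_RIS_rep1.bed")))
  tr <- utils::read.delim(file.path(out, "truth.tsv"))
  expect_equal(sum(tr$is_target), cfg$n_target_genes)
  unlink(out, recursive = TRUE)
})
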