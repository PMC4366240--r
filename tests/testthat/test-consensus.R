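test_that("within-condition clustering counts distinct replicates, not peaks", {
  pk <- peaks_from_df(data.frame(cond = "RIS", rep = c(1, 2),
                                 start = c(100, 150), end = c(200, 250)))
  cl <- cluster_within_condition(pk)
  expect_length(cl, 1)
  expect_equal(S4Vectors::mcols(cl)$support, 2L)
  expect_true(S4Vectors::mcols(cl)$replicated)
  expect_equal(c(start0(cl), end0(cl)), c(100, 250))

  solo <- cluster_within_condition(peaks_from_df(
    data.frame(cond = "RIS", rep = 1, start = 100, end = 200)))
  expect_false(S4Vectors::mcols(solo)$replicated)

  same_rep <- cluster_within_condition(peaks_from_df(
    data.frame(cond = "RIS", rep = c(1, 1), start = c(100, 150),
               end = c(200, 250))))
  expect_length(same_rep, 1)
  expect_equal(S4Vectors::mcols(same_rep)$support, 1L)
  expect_false(S4Vectors::mcols(same_rep)$replicated)

  expect_length(cluster_within_condition(GenomicRanges::GRanges()), 0)
  mixed <- peaks_from_df(data.frame(cond = c("RIS", "pApo"), rep = 1,
                                    start = c(1, 2), end = c(10, 20)))
  expect_error(cluster_within_condition(mixed), "several conditions")
})

test_that("singleton rescue applies the two cross-condition rules", {
  mk_all <- function(df) peaks_from_df(df)
  singleton <- function() cluster_within_condition(peaks_from_df(
    data.frame(cond = "RIS", rep = 1, start = 100, end = 200)))

  # rule (i): one acDDR peak and one pApo peak
  all1 <- mk_all(data.frame(cond = c("RIS", "acDDR", "pApo"), rep = 1,
                            start = c(100, 120, 150), end = c(200, 220, 250)))
  r1 <- rescue_singletons(singleton(), all1)
  expect_true(S4Vectors::mcols(r1)$rescued)
  expect_equal(S4Vectors::mcols(r1)$rule, "i")

  # rule (ii): two replicates of pApo
  all2 <- mk_all(data.frame(cond = c("RIS", "pApo", "pApo"), rep = c(1, 1, 2),
                            start = c(100, 120, 150), end = c(200, 220, 250)))
  r2 <- suppressWarnings(rescue_singletons(singleton(), all2))
  expect_true(S4Vectors::mcols(r2)$rescued)
  expect_equal(S4Vectors::mcols(r2)$rule, "ii")

  # neither: a single peak in a single other condition
  all3 <- mk_all(data.frame(cond = c("RIS", "pApo"), rep = 1,
                            start = c(100, 120), end = c(200, 220)))
  r3 <- suppressWarnings(rescue_singletons(singleton(), all3))
  expect_false(S4Vectors::mcols(r3)$rescued)

  # two same-condition peaks from ONE replicate satisfy neither rule
  all4 <- mk_all(data.frame(cond = c("RIS", "pApo", "pApo"), rep = 1,
                            start = c(100, 120, 150), end = c(200, 220, 250)))
  r4 <- suppressWarnings(rescue_singletons(singleton(), all4))
  expect_false(S4Vectors::mcols(r4)$rescued)

  # with only 2 conditions present, rule (i) is unattainable: warn
  expect_warning(rescue_singletons(singleton(), all3), "rule \\(i\\)")
})

test_that("strict rescue only counts partners from replicated clusters", {
  singleton <- cluster_within_condition(peaks_from_df(
    data.frame(cond = "RIS", rep = 1, start = 100, end = 200)))
  # partner peaks: singletons themselves in acDDR and pApo
  allp <- peaks_from_df(data.frame(
    cond = c("RIS", "acDDR", "pApo"), rep = 1,
    start = c(100, 120, 150), end = c(200, 220, 250)))
  expect_true(S4Vectors::mcols(
    rescue_singletons(singleton, allp, strict = FALSE))$rescued)
  expect_false(S4Vectors::mcols(
    rescue_singletons(singleton, allp, strict = TRUE))$rescued)
})

test_that("HC set merges replicated and rescued spans with provenance", {
  df <- data.frame(
    cond = c("RIS", "RIS", "RIS", "acDDR", "pApo"),
    rep = c(1, 2, 3, 1, 1),
    start = c(100, 150, 240, 250, 260),
    end = c(200, 250, 300, 320, 330))
  # reps 1+2 form a replicated cluster [100,250); rep3 [240,300) overlaps it,
  # so everything is one cluster; move rep3 out to make a rescued singleton
  df$start[3] <- 400; df$end[3] <- 500
  df$start[4] <- 420; df$end[4] <- 520
  df$start[5] <- 430; df$end[5] <- 530
  hc <- build_hc_peakset(peaks_from_df(df))
  ris <- hc$hc$RIS
  expect_equal(start0(ris), c(100, 400))
  expect_equal(end0(ris), c(250, 500))
  expect_setequal(S4Vectors::mcols(ris)$provenance, c("replicated", "rescued"))
  expect_true(all(c("replicated", "rescued_i") %in% hc$audit$status))

  # an abutting same-replicate peak extends the cluster span: one HC peak
  df2 <- data.frame(cond = c("RIS", "RIS", "RIS", "acDDR", "pApo"),
                    rep = c(1, 2, 1, 1, 1),
                    start = c(100, 150, 240, 245, 250),
                    end = c(200, 240, 300, 330, 340))
  hc2 <- build_hc_peakset(peaks_from_df(df2))
  expect_equal(start0(hc2$hc$RIS), 100)
  expect_equal(end0(hc2$hc$RIS), 300)
  expect_equal(S4Vectors::mcols(hc2$hc$RIS)$provenance, "replicated")

  # condition with nothing admissible gets an empty HC set
  lonely <- peaks_from_df(data.frame(cond = c("Grow", "RIS"), rep = 1,
                                     start = c(1000, 5000),
                                     end = c(1100, 5100)))
  hc3 <- suppressWarnings(build_hc_peakset(lonely))
  expect_length(hc3$hc$Grow, 0)
})

test_that("consensus matches the per-base oracle on random instances", {
  set.seed(403)
  for (i in 1:200) {
    df <- rand_peak_instance()
    got <- suppressWarnings(build_hc_peakset(peaks_from_df(df)))$hc
    want <- brute_hc(df)
    for (cc in unique(df$cond)) {
      gmask <- if (cc %in% names(got)) mask_of_granges(got[[cc]])
               else rep(FALSE, 10000)
      expect_identical(gmask, want[[cc]],
                       label = sprintf("instance %d condition %s", i, cc))
    }
  }
})

test_that("adding a peak never removes HC bases (monotonicity)", {
  set.seed(404)
  for (i in 1:40) {
    df <- rand_peak_instance()
    base <- suppressWarnings(build_hc_peakset(peaks_from_df(df)))$hc
    extra <- rand_peak_instance(max_peaks = 1)
    got <- suppressWarnings(build_hc_peakset(peaks_from_df(rbind(df, extra))))$hc
    for (cc in names(base)) {
      before <- mask_of_granges(base[[cc]])
      after <- if (cc %in% names(got)) mask_of_granges(got[[cc]])
               else rep(FALSE, 10000)
      expect_true(all(after[before]), label = sprintf("instance %d", i))
    }
  }
})

test_that("every HC peak overlaps at least one input peak", {
  set.seed(405)
  for (i in 1:25) {
    df <- rand_peak_instance()
    pk <- peaks_from_df(df)
    hc <- suppressWarnings(build_hc_peakset(pk))$hc
    for (cc in names(hc)) {
      if (length(hc[[cc]]) == 0) next
      expect_true(all(GenomicRanges::countOverlaps(
        hc[[cc]], pk, ignore.strand = TRUE) > 0))
    }
  }
})
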