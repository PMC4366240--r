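# Independent brute-force oracles and small fixture builders used across the
# suite. Everything here is deliberately naive (per-base bitmaps, explicit
# enumeration) so it shares no code path with the implementation it checks.

# --- interval / consensus oracles -----------------------------------------

# per-base union of 0-based half-open intervals on a toy chromosome
merge_oracle_mask <- function(start, end, chrom_len = 10000) {
  mask <- rep(FALSE, chrom_len)
  for (i in seq_along(start)) mask[(start[i] + 1):end[i]] <- TRUE
  mask
}

mask_of_granges <- function(gr, chrom_len = 10000) {
  mask <- rep(FALSE, chrom_len)
  for (i in seq_along(gr)) mask[(start0(gr)[i] + 1):end0(gr)[i]] <- TRUE
  mask
}

# maximal TRUE runs of a mask as 0-based half-open intervals
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values] - 1, end = ends[r$values])
}

# Literal per-base application of the three consensus sentences: replicated
# runs; singleton runs rescued by >=2 other conditions or >=2 replicates of
# one other condition; kept bases form the HC set.
brute_hc <- function(df, chrom_len = 10000) {
  out <- list()
  for (cc in unique(df$cond)) {
    pk <- df[df$cond == cc, , drop = FALSE]
    runs <- mask_runs(merge_oracle_mask(pk$start, pk$end, chrom_len))
    keep <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      mine <- pk[pk$start < e & s < pk$end, , drop = FALSE]
      if (length(unique(mine$rep)) >= 2) {
        keep[(s + 1):e] <- TRUE
        next
      }
      oth <- df[df$cond != cc & df$start < e & s < df$end, , drop = FALSE]
      if (nrow(oth) == 0) next
      rule_i <- length(unique(oth$cond)) >= 2
      rule_ii <- any(tapply(oth$rep, oth$cond,
                            function(r) length(unique(r))) >= 2)
      if (rule_i || rule_ii) keep[(s + 1):e] <- TRUE
    }
    out[[cc]] <- keep
  }
  out
}

rand_peak_instance <- function(max_peaks = 20, chrom_len = 10000) {
  n <- sample.int(max_peaks, 1)
  nreps <- c(Grow = 2L, acDDR = 3L, RIS = 3L, pApo = 3L)
  cond <- sample(names(nreps), n, replace = TRUE)
  repl <- vapply(cond, function(cc) sample.int(nreps[[cc]], 1), 0L,
                 USE.NAMES = FALSE)
  start <- sample.int(chrom_len - 600, n)
  width <- sample(50:500, n, replace = TRUE)
  data.frame(cond = cond, rep = repl, start = start,
             end = pmin(start + width, chrom_len))
}

peaks_from_df <- function(df) {
  peak_set(gi("chr", df$start, df$end), score = 1,
           condition = df$cond, replicate = df$rep)
}

# --- statistics oracles -----------------------------------------------------

# exhaustive BH step-up: sort descending, cumulative minimum of p * m / rank
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  cm <- 1
  for (i in seq_along(o)) {
    rank <- m - i + 1
    cm <- min(cm, p[o[i]] * m / rank)
    q[o[i]] <- cm
  }
  q
}

pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

auroc <- function(score, label) {
  r <- rank(score)
  (mean(r[label]) - (sum(label) + 1) / 2) / sum(!label)
}

# --- motif oracles ----------------------------------------------------------

# every same-strand ordered pair of half hits with a gap in [smin, smax]
full_site_pairs_oracle <- function(halves, L, smin = 0, smax = 13) {
  out <- list()
  for (st in unique(halves$strand)) {
    h <- halves[halves$strand == st, , drop = FALSE]
    h <- h[order(h$position), , drop = FALSE]
    if (nrow(h) < 2) next
    for (i in seq_len(nrow(h) - 1)) for (j in (i + 1):nrow(h)) {
      gap <- h$position[j] - (h$position[i] + L)
      if (gap >= smin && gap <= smax)
        out[[length(out) + 1]] <- data.frame(
          start = h$position[i], end = h$position[j] + L, strand = st,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    data.frame(start = integer(), end = integer(), strand = character())
  else unique(do.call(rbind, out))
}

# --- fixtures ---------------------------------------------------------------

toy_genome <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    tss = c(100000L, 300000L),
    tes = c(109999L, 290001L),
    exon_starts = c("100000,104500,109500", "290001,294500,299500"),
    exon_ends = c("100500,105500,110000", "290501,295500,300000"),
    probe_ids = c("pA", "pB"),
    stringsAsFactors = FALSE)
  cgis <- gi("chr1", 99500, 100500)
  genome_model(genes, cgis, chrom_sizes = c(chr1 = 1000000L))
}

chip_samples <- function(cond = "c", n_chip = 3, n_input = n_chip) {
  data.frame(
    sample_id = c(sprintf("%s_chip_rep%d", cond, seq_len(n_chip)),
                  sprintf("%s_input_rep%d", cond, seq_len(n_input))),
    role = rep(c("chip", "input"), c(n_chip, n_input)),
    condition = cond,
    replicate = c(seq_len(n_chip), seq_len(n_input)),
    stringsAsFactors = FALSE)
}

small_config <- function(...) {
  defaults <- list(n_genes = 50, chrom_length = 50 * 125000,
                   n_bound_genes = 10, n_responsive_genes = 8,
                   n_target_genes = 6)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
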