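#' Simulation configuration
#'
#' Defines the synthetic study: a toy genome of well-separated genes on one
#' chromosome, four ChIP conditions with the study's replicate structure
#' (Grow 2 replicates; acDDR, RIS and pApo 3 each), a 3 vs 3
#' knockdown-versus-vector expression contrast, and planted ground truth
#' (bound genes, responsive genes, and their intersection: the direct
#' targets). Targets are drawn preferentially from CGI-promoter genes.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp; genes are spaced evenly and
#'   the spacing must be at least 120 kb.
#' @param cgi_promoter_fraction fraction of genes whose promoter overlaps a
#'   CpG island.
#' @param conditions named integer vector: ChIP replicate count per condition.
#' @param n_expr_replicates arrays per expression arm.
#' @param n_bound_genes,n_responsive_genes,n_target_genes planted counts;
#'   targets are bound AND responsive, extra bound/responsive genes are
#'   disjoint from each other.
#' @param frac_repressed fraction of responsive genes repressed by p53
#'   (up under knockdown).
#' @param cgi_target_odds odds ratio favouring CGI-promoter genes when
#'   drawing targets.
#' @param chip_mean_background mean input/background reads per TSS bin.
#' @param chip_fold_enrichment ChIP/input fold change at bound genes.
#' @param nb_dispersion negative-binomial dispersion phi (Var = mu + phi mu^2).
#' @param expr_sd per-array log2 noise SD.
#' @param expr_effect knockdown effect size in log2 units; induced targets
#'   move down by this amount under sh-p53, repressed targets move up.
#' @param peak_width replicate peak width in bp.
#' @param peak_jitter_sd SD of the Gaussian jitter of peak centres around
#'   the TSS.
#' @param peak_dropout_prob per-replicate probability that a bound gene's
#'   peak is missed.
#' @param decoy_frac decoy singleton peaks per condition, as a fraction of
#'   the gene count.
#' @param seed integer seed; every generator derives its stream from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       chrom_length = 242e6,
                       cgi_promoter_fraction = 0.5,
                       conditions = c(Grow = 2L, acDDR = 3L, RIS = 3L, pApo = 3L),
                       n_expr_replicates = 3L,
                       n_bound_genes = 250L,
                       n_responsive_genes = 200L,
                       n_target_genes = 150L,
                       frac_repressed = 0.2,
                       cgi_target_odds = 3,
                       chip_mean_background = 20,
                       chip_fold_enrichment = 5,
                       nb_dispersion = 0.1,
                       expr_sd = 0.3,
                       expr_effect = 1.0,
                       peak_width = 250L,
                       peak_jitter_sd = 50,
                       peak_dropout_prob = 0.2,
                       decoy_frac = 0.1,
                       seed = 20150319L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_genes >= 1, chrom_length > 0,
              cgi_promoter_fraction >= 0, cgi_promoter_fraction <= 1,
              length(conditions) >= 1, all(conditions >= 1),
              !is.null(names(conditions)),
              n_expr_replicates >= 2,
              n_bound_genes >= 0, n_responsive_genes >= 0,
              n_target_genes >= 0,
              n_target_genes <= n_bound_genes,
              n_target_genes <= n_responsive_genes,
              n_bound_genes <= n_genes, n_responsive_genes <= n_genes,
              frac_repressed >= 0, frac_repressed <= 1,
              cgi_target_odds > 0,
              chip_mean_background > 0, chip_fold_enrichment > 0,
              nb_dispersion > 0, expr_sd > 0, expr_effect >= 0,
              peak_width >= 1, peak_jitter_sd >= 0,
              peak_dropout_prob >= 0, peak_dropout_prob <= 1,
              decoy_frac >= 0)
  })
  structure(cfg, class = "sim_config")
}

# Run expr under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Simulate the toy genome
#'
#' Genes are placed on one synthetic chromosome at even spacing (>= 120 kb so
#' promoter, distal and intergenic peak classes are all realizable) on
#' alternating strands, with three exons each. A seeded subset of
#' \code{cgi_promoter_fraction} genes receives a 1 kb CpG island spanning
#' [TSS-500, TSS+500).
#'
#' @param config a [sim_config()].
#' @return A [genome_model()]; \code{genes} carries an extra
#'   \code{cgi_promoter} flag.
#' @export
simulate_genome <- function(config) {
  spacing <- floor(config$chrom_length / config$n_genes)
  if (spacing < 120000)
    stop("chrom_length too small: gene spacing would be ", spacing,
         " bp (< 120 kb); enlarge chrom_length or reduce n_genes")
  with_seed(config$seed + 1L, {
    n <- config$n_genes
    anchor <- round((seq_len(n) - 0.5) * spacing)
    strand <- rep(c("+", "-"), length.out = n)
    len <- sample(5000:30000, n, replace = TRUE)
    tss <- anchor
    tes <- ifelse(strand == "+", tss + len - 1L, tss - len + 1L)
    body_start <- pmin(tss, tes)
    body_end <- pmax(tss, tes)    # inclusive
    gene_id <- sprintf("G%04d", seq_len(n))
    mid <- floor((body_start + body_end) / 2)
    exon_starts <- paste(body_start, mid - 250L, body_end - 499L, sep = ",")
    exon_ends <- paste(body_start + 500L, mid + 250L, body_end + 1L, sep = ",")
    genes <- data.frame(gene_id = gene_id, chrom = "chrS", strand = strand,
                        tss = tss, tes = tes,
                        exon_starts = exon_starts, exon_ends = exon_ends,
                        probe_ids = paste0("P_", gene_id),
                        stringsAsFactors = FALSE)
    n_cgi <- round(config$cgi_promoter_fraction * n)
    cgi_genes <- sort(sample.int(n, n_cgi))
    genes$cgi_promoter <- seq_len(n) %in% cgi_genes
    cgis <- if (n_cgi > 0)
      gi("chrS", tss[cgi_genes] - 500L, tss[cgi_genes] + 500L)
    else GenomicRanges::GRanges()
    genome_model(genes, cgis,
                 chrom_sizes = c(chrS = as.integer(config$chrom_length)))
  })
}

#' Plant the ground truth
#'
#' Draws exactly \code{n_target_genes} direct targets (bound AND responsive)
#' with sampling weights \code{cgi_target_odds} : 1 favouring CGI-promoter
#' genes, then disjoint extra bound-only and responsive-only genes uniformly
#' from the remainder. Responsive genes are repressed with probability
#' \code{frac_repressed}, induced otherwise.
#'
#' @param genome from [simulate_genome()].
#' @param config a [sim_config()].
#' @return data.frame (one row per gene): \code{gene_id}, \code{bound},
#'   \code{responsive}, \code{direction} (induced/repressed/none),
#'   \code{is_target}, \code{promoter_class} (CGI/nonCGI).
#' @export
plant_truth <- function(genome, config) {
  n <- nrow(genome$genes)
  n_extra <- (config$n_bound_genes - config$n_target_genes) +
    (config$n_responsive_genes - config$n_target_genes)
  if (config$n_target_genes + n_extra > n)
    stop("requested bound/responsive counts exceed the gene pool")
  with_seed(config$seed + 2L, {
    cgi <- genome$genes$cgi_promoter
    w <- ifelse(cgi, config$cgi_target_odds, 1)
    targets <- if (config$n_target_genes > 0)
      sample.int(n, config$n_target_genes, prob = w) else integer(0)
    rest <- setdiff(seq_len(n), targets)
    extra_bound <- config$n_bound_genes - config$n_target_genes
    extra_resp <- config$n_responsive_genes - config$n_target_genes
    picks <- if (n_extra > 0) sample(rest, n_extra) else integer(0)
    bound_only <- picks[seq_len(extra_bound)]
    resp_only <- picks[extra_bound + seq_len(extra_resp)]
    bound <- seq_len(n) %in% c(targets, bound_only)
    responsive <- seq_len(n) %in% c(targets, resp_only)
    direction <- rep("none", n)
    nresp <- sum(responsive)
    direction[responsive] <- ifelse(
      stats::runif(nresp) < config$frac_repressed, "repressed", "induced")
    data.frame(gene_id = genome$genes$gene_id,
               bound = bound, responsive = responsive,
               direction = direction,
               is_target = bound & responsive,
               promoter_class = ifelse(cgi, "CGI", "nonCGI"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate ChIP-seq data: peaks, reads and TSS-bin counts
#'
#' Bound genes receive one peak per replicate in every condition, centred on
#' the TSS with Gaussian jitter and dropped with probability
#' \code{peak_dropout_prob}; decoy peaks at random non-bound loci appear in
#' exactly one replicate. ChIP bin counts at bound genes are
#' NB(background x fold, phi), input and unbound counts NB(background, phi);
#' read positions are drawn uniformly within each gene's TSS window from the
#' counts, so recounting reads reproduces the count table exactly.
#'
#' @param genome from [simulate_genome()].
#' @param truth from [plant_truth()].
#' @param config a [sim_config()].
#' @return list with \code{peaks} (\code{GRanges} with condition/replicate/
#'   score mcols), \code{reads} (named list of 0-based positions per sample)
#'   and \code{counts} (a [bin_count_table()]).
#' @export
simulate_chip <- function(genome, truth, config) {
  with_seed(config$seed + 3L, {
    genes <- genome$genes
    n <- nrow(genes)
    bound_idx <- which(truth$bound)
    size <- 1 / config$nb_dispersion

    ## --- peaks -----------------------------------------------------------
    pk <- list()
    for (cond in names(config$conditions)) {
      n_rep <- config$conditions[[cond]]
      for (r in seq_len(n_rep)) {
        present <- bound_idx[stats::runif(length(bound_idx)) >=
                               config$peak_dropout_prob]
        if (length(present) > 0) {
          centre <- genes$tss[present] +
            round(stats::rnorm(length(present), 0, config$peak_jitter_sd))
          st <- pmax(centre - floor(config$peak_width / 2), 0)
          pk[[length(pk) + 1L]] <- peak_set(
            gi("chrS", st, st + config$peak_width),
            score = round(stats::runif(length(present), 50, 300), 1),
            condition = cond, replicate = r)
        }
      }
      n_decoy <- round(config$decoy_frac * n)
      if (n_decoy > 0) {
        pos <- sample.int(config$chrom_length - config$peak_width, n_decoy)
        reps <- sample.int(n_rep, n_decoy, replace = TRUE)
        pk[[length(pk) + 1L]] <- peak_set(
          gi("chrS", pos, pos + config$peak_width),
          score = round(stats::runif(n_decoy, 50, 150), 1),
          condition = cond, replicate = reps)
      }
    }
    peaks <- do.call(c, pk)

    ## --- counts and reads ------------------------------------------------
    win <- tss_windows(genes)
    samples <- do.call(rbind, lapply(names(config$conditions), function(cond) {
      n_rep <- config$conditions[[cond]]
      data.frame(
        sample_id = c(sprintf("%s_chip_rep%d", cond, seq_len(n_rep)),
                      sprintf("%s_input_rep%d", cond, seq_len(n_rep))),
        role = rep(c("chip", "input"), each = n_rep),
        condition = cond,
        replicate = c(seq_len(n_rep), seq_len(n_rep)),
        stringsAsFactors = FALSE)
    }))
    mu_chip <- ifelse(truth$bound,
                      config$chip_mean_background * config$chip_fold_enrichment,
                      config$chip_mean_background)
    mu_input <- rep(config$chip_mean_background, n)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(genes$gene_id, samples$sample_id))
    reads <- vector("list", nrow(samples))
    names(reads) <- samples$sample_id
    for (j in seq_len(nrow(samples))) {
      mu <- if (samples$role[j] == "chip") mu_chip else mu_input
      cnt <- stats::rnbinom(n, mu = mu, size = size)
      counts[, j] <- cnt
      g_of_read <- rep.int(seq_len(n), cnt)
      width <- win$end - win$start
      reads[[j]] <- win$start[g_of_read] +
        floor(stats::runif(length(g_of_read)) * width[g_of_read])
    }
    list(peaks = peaks, reads = reads,
         counts = bin_count_table(counts, samples))
  })
}

#' Simulate the knockdown-versus-vector expression matrices
#'
#' Per-probe log2 intensities are Normal(baseline, expr_sd); in the sh-p53
#' arm, responsive probes shift by -expr_effect (induced targets: expression
#' drops when p53 is depleted) or +expr_effect (repressed targets).
#'
#' @param genome from [simulate_genome()].
#' @param truth from [plant_truth()].
#' @param config a [sim_config()].
#' @return list of two probes-by-replicates matrices, \code{vector} and
#'   \code{shp53}.
#' @export
simulate_expression <- function(genome, truth, config) {
  with_seed(config$seed + 4L, {
    n <- nrow(genome$genes)
    k <- config$n_expr_replicates
    probes <- genome$genes$probe_ids
    baseline <- stats::rnorm(n, 8, 1)
    shift <- ifelse(truth$direction == "induced", -config$expr_effect,
                    ifelse(truth$direction == "repressed",
                           config$expr_effect, 0))
    vec <- baseline + matrix(stats::rnorm(n * k, 0, config$expr_sd), n, k)
    sh <- baseline + shift +
      matrix(stats::rnorm(n * k, 0, config$expr_sd), n, k)
    dimnames(vec) <- list(probes, sprintf("vector_rep%d", seq_len(k)))
    dimnames(sh) <- list(probes, sprintf("shp53_rep%d", seq_len(k)))
    list(vector = vec, shp53 = sh)
  })
}

#' Simulate a complete study
#'
#' Runs [simulate_genome()], [plant_truth()], [simulate_chip()] and
#' [simulate_expression()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list with \code{genome}, \code{truth}, \code{chip}, \code{expr}
#'   and the \code{config} itself.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  truth <- plant_truth(genome, config)
  list(genome = genome, truth = truth,
       chip = simulate_chip(genome, truth, config),
       expr = simulate_expression(genome, truth, config),
       config = config)
}

#' Write a simulated dataset to a directory
#'
#' Emits genes.tsv, cgis.bed, truth.tsv, per-condition-replicate peak BEDs,
#' counts.tsv (+ counts_samples.tsv annotations) and the two expression
#' matrices; optionally one BED of read positions per sample.
#'
#' @param ds from [simulate_dataset()].
#' @param outdir output directory (created if needed).
#' @param write_reads also write per-sample read-position BEDs (large).
#' @return \code{outdir}, invisibly.
#' @export
write_dataset <- function(ds, outdir, write_reads = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  write_gene_table(ds$genome$genes, fp("genes.tsv"))
  if (length(ds$genome$cgis) > 0) write_bed(ds$genome$cgis, fp("cgis.bed"))
  utils::write.table(ds$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pk <- ds$chip$peaks
  key <- paste0(S4Vectors::mcols(pk)$condition, "_rep",
                S4Vectors::mcols(pk)$replicate)
  for (k in unique(key)) {
    sub <- pk[key == k]
    S4Vectors::mcols(sub)$name <-
      sprintf("%s_peak%d", k, seq_along(sub))
    write_bed(sub, fp(sprintf("peaks_%s.bed", k)))
  }
  write_matrix_tsv(ds$chip$counts$counts, fp("counts.tsv"), id_col = "gene_id")
  utils::write.table(ds$chip$counts$samples, fp("counts_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(ds$expr$vector, fp("expr_vector.tsv"), id_col = "probe_id")
  write_matrix_tsv(ds$expr$shp53, fp("expr_shp53.tsv"), id_col = "probe_id")
  if (write_reads) {
    for (s in names(ds$chip$reads)) {
      pos <- ds$chip$reads[[s]]
      if (length(pos) > 0)
        write_bed(gi("chrS", pos, pos + 1L), fp(sprintf("reads_%s.bed", s)))
    }
  }
  invisible(outdir)
}
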