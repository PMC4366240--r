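#' TSS-bin count table
#'
#' Genes-by-samples integer counts with sample annotations and effective
#' library sizes (the bin count sums).
#'
#' @param counts non-negative integer matrix, rownames = gene ids.
#' @param samples data.frame with columns \code{sample_id}, \code{role}
#'   (chip/input), \code{condition}, \code{replicate}, one row per column
#'   of \code{counts}.
#' @return list of class \code{bin_count_table} with \code{counts},
#'   \code{samples} and \code{library_sizes}.
#' @export
bin_count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(nrow(samples) == ncol(counts),
            all(c("sample_id", "role", "condition", "replicate") %in%
                  names(samples)),
            all(samples$role %in% c("chip", "input")))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, samples = samples,
                 library_sizes = colSums(counts)),
            class = "bin_count_table")
}

#' @export
print.bin_count_table <- function(x, ...) {
  cat("bin_count_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$samples$role == "chip"), "chip /",
      sum(x$samples$role == "input"), "input )\n")
  invisible(x)
}

#' Count reads in TSS-local bins
#'
#' One strand-aware window per gene covering 50 bp upstream to 1500 bp
#' downstream of the TSS (for a + gene, [TSS-50, TSS+1500) in 0-based
#' half-open coordinates; mirrored for - genes). A read is a single
#' position; reads falling in two genes' overlapping windows count in both.
#'
#' @param reads named list of 0-based integer read positions, one element
#'   per sample.
#' @param genome a [genome_model()].
#' @param upstream,downstream window extent in bp around the TSS.
#' @param samples optional sample annotation data.frame (see
#'   [bin_count_table()]); when omitted, sample ids of the form
#'   \code{<condition>_<role>_rep<k>} are parsed from \code{names(reads)}.
#' @return A [bin_count_table()].
#' @export
count_bin_reads <- function(reads, genome, upstream = 50L, downstream = 1500L,
                            samples = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  genes <- genome$genes
  win <- tss_windows(genes, upstream, downstream)
  max_len <- max(genome$chrom_sizes)
  counts <- matrix(0L, nrow(genes), length(reads),
                   dimnames = list(genes$gene_id, names(reads)))
  for (j in seq_along(reads)) {
    pos <- reads[[j]]
    if (length(pos) == 0) next
    if (any(pos < 0) || any(pos >= max_len))
      stop("read position outside chromosome bounds in sample ",
           names(reads)[j])
    sp <- sort(pos)
    counts[, j] <- findInterval(win$end - 1L, sp) -
      findInterval(win$start - 1L, sp)
  }
  if (is.null(samples)) samples <- parse_sample_ids(names(reads))
  bin_count_table(counts, samples)
}

parse_sample_ids <- function(ids) {
  parts <- regmatches(ids, regexec("^(.*)_(chip|input)_rep([0-9]+)$", ids))
  if (any(lengths(parts) != 4))
    stop("cannot parse sample ids; supply a samples annotation data.frame")
  data.frame(sample_id = ids,
             role = vapply(parts, `[`, "", 3),
             condition = vapply(parts, `[`, "", 2),
             replicate = as.integer(vapply(parts, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Between-sample count normalization
#'
#' \code{libsize}: divide each column by its effective library size (its
#' bin count sum) and rescale to the mean library size, so column sums are
#' equal. \code{quantile}: quantile-based effective library sizes in the
#' baySeq sense - each sample's size factor is the sum of its counts at or
#' below its 75th count percentile, which is robust to the enriched upper
#' tail of ChIP samples - then the same division and rescale.
#'
#' @param table a [bin_count_table()].
#' @param method \code{"quantile"} (default) or \code{"libsize"}.
#' @param quantile_p percentile defining the quantile library size.
#' @return list: \code{normalized} (numeric matrix), \code{factors}
#'   (per-sample size factors, mean 1), \code{method}.
#' @export
normalize_counts <- function(table, method = c("quantile", "libsize"),
                             quantile_p = 0.75) {
  method <- match.arg(method)
  cnt <- table$counts
  size <- switch(method,
    libsize = colSums(cnt),
    quantile = vapply(seq_len(ncol(cnt)), function(j) {
      x <- cnt[, j]
      sum(x[x <= stats::quantile(x, quantile_p)])
    }, 0))
  if (any(size <= 0))
    stop("zero effective library size in sample(s): ",
         paste(colnames(cnt)[size <= 0], collapse = ", "))
  factors <- size / mean(size)
  normalized <- sweep(cnt, 2, factors, "/")
  list(normalized = normalized, factors = factors, method = method)
}

#' Method-of-moments NB dispersion estimate
#'
#' Pools the within-group (chip and input separately) mean/variance pairs
#' across genes on the normalized scale and solves
#' \eqn{Var = \mu + \phi \mu^2} by the ratio-of-sums estimator.
#'
#' @param cnt normalized count matrix.
#' @param role per-column roles (chip/input).
#' @return Dispersion \eqn{\phi > 0} (floored at 1e-4).
#' @export
estimate_dispersion <- function(cnt, role) {
  num <- 0; den <- 0
  for (r in unique(role)) {
    x <- cnt[, role == r, drop = FALSE]
    if (ncol(x) < 2) next
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  if (den == 0) return(0.1)
  max(num / den, 1e-4)
}

#' Posterior probability of ChIP enrichment over input
#'
#' Per gene, compares two negative-binomial models of the TSS-bin counts of
#' one condition: M0, chip and input share one underlying rate (per-sample
#' mean = rate x size factor); M1, chip rate strictly greater than input
#' rate. Marginal likelihoods integrate the NB likelihood (dispersion
#' \code{phi}) over a discrete empirical rate prior built by bootstrap
#' resampling of per-gene pooled rates (50 genes x 100 draws, coarsened to
#' \code{grid_size} quantile mass points and extended with log-spaced tail
#' points to cover the extreme per-gene arm rates). M1 uses the product of
#' two rate priors restricted to the ordered cone without renormalization,
#' so the ordered alternative pays its natural prior-mass (Occam) penalty
#' and equal chip/input counts favour the shared-rate model. The posterior
#' is
#' \deqn{pC = \pi L(M1) / (\pi L(M1) + (1-\pi) L(M0)).}
#'
#' The model prior \eqn{\pi} defaults to empirical-Bayes estimation by a
#' mean-posterior fixed point (iterate \eqn{\pi \leftarrow mean(pC)}), the
#' same idea baySeq uses to estimate model priors from the data; pass a
#' number (e.g. 0.5) to fix it.
#'
#' @param table a [bin_count_table()].
#' @param condition condition to analyse; required when the table holds
#'   several.
#' @param phi NB dispersion; method-of-moments estimate when \code{NULL}.
#' @param pi prior probability of enrichment, or \code{NULL} to estimate.
#' @param norm normalization method, see [normalize_counts()].
#' @param grid_size number of rate-grid mass points.
#' @param n_boot_genes,n_boot_draws bootstrap design for the rate prior.
#' @return data.frame per gene: \code{gene}, \code{chip_mean},
#'   \code{input_mean} (normalized), \code{pC}, \code{flagged} (all-zero
#'   rows, where the prior is returned); attributes \code{phi} and
#'   \code{pi}.
#' @export
enrichment_posterior <- function(table, condition = NULL, phi = NULL,
                                 pi = NULL, norm = c("quantile", "libsize"),
                                 grid_size = 24L,
                                 n_boot_genes = 50L, n_boot_draws = 100L) {
  norm <- match.arg(norm)
  samp <- table$samples
  conds <- unique(samp$condition)
  if (is.null(condition)) {
    if (length(conds) > 1)
      stop("table holds conditions ", paste(conds, collapse = ", "),
           "; pick one via `condition`")
    condition <- conds
  }
  keep <- samp$condition == condition
  if (sum(keep & samp$role == "chip") < 1 ||
      sum(keep & samp$role == "input") < 1)
    stop("need at least one chip and one input sample for ", condition)
  sub <- bin_count_table(table$counts[, keep, drop = FALSE],
                         samp[keep, , drop = FALSE])
  nrm <- normalize_counts(sub, method = norm)
  f <- nrm$factors
  role <- sub$samples$role
  cnt <- sub$counts
  is_chip <- role == "chip"
  if (is.null(phi)) phi <- estimate_dispersion(nrm$normalized, role)
  size <- 1 / phi

  ## empirical rate grid from bootstrapped per-gene pooled rates
  ng <- nrow(cnt)
  gsel <- sample.int(ng, min(n_boot_genes, ng))
  rates <- unlist(lapply(gsel, function(g) {
    y <- cnt[g, ] / f
    vapply(seq_len(n_boot_draws), function(i)
      mean(y[sample.int(length(y), replace = TRUE)]), 0)
  }))
  rates <- rates[rates > 0]
  if (length(rates) == 0) rates <- 1
  grid <- unique(stats::quantile(rates, probs = seq(0.5, grid_size - 0.5) /
                                   grid_size, names = FALSE, type = 1))
  grid <- sort(pmax(grid, 1e-3))
  ## extend with log-spaced tail points so the grid spans every per-gene
  ## arm-level rate (bootstrap quantiles alone can miss rare extremes)
  nm0 <- sweep(cnt, 2, f, "/")
  arm <- c(rowMeans(nm0[, is_chip, drop = FALSE]),
           rowMeans(nm0[, !is_chip, drop = FALSE]))
  hi <- max(arm); lo <- max(min(arm), 1e-3)
  if (hi > max(grid) * 1.05)
    grid <- c(grid, exp(seq(log(max(grid)), log(hi), length.out = 7))[-1])
  if (lo < min(grid) / 1.05)
    grid <- c(grid, exp(seq(log(lo), log(min(grid)), length.out = 4))[-4])
  grid <- sort(unique(grid))
  K <- length(grid)
  w <- rep(1 / K, K)

  ## per-gene log-likelihood over the grid, chip and input arms separately
  ll_arm <- function(cols) {
    out <- matrix(0, ng, K)
    for (k in seq_len(K)) {
      mu <- outer(rep(grid[k], ng), f[cols])
      out[, k] <- rowSums(stats::dnbinom(cnt[, cols, drop = FALSE],
                                         mu = mu, size = size, log = TRUE))
    }
    out
  }
  A <- ll_arm(which(is_chip))
  B <- ll_arm(which(!is_chip))
  sa <- apply(A, 1, max)
  sb <- apply(B, 1, max)
  EA <- exp(A - sa)
  EB <- exp(B - sb)
  L0 <- as.vector((EA * EB) %*% w)
  ## ordered alternative: sum over grid pairs with chip rate > input rate
  cumEBw <- t(apply(sweep(EB, 2, w, "*"), 1, cumsum))
  prevEBw <- cbind(0, cumEBw[, -K, drop = FALSE])
  L1 <- if (K < 2) rep(0, ng)
        else as.vector(rowSums(sweep(EA, 2, w, "*") * prevEBw))

  post <- function(pi) {
    pc <- pi * L1 / (pi * L1 + (1 - pi) * L0)
    pc[is.na(pc)] <- pi   # both likelihoods underflowed
    pc
  }
  if (is.null(pi)) {
    pi_hat <- 0.5
    for (it in 1:25) {
      newpi <- min(max(mean(post(pi_hat)), 1e-3), 0.5)
      if (abs(newpi - pi_hat) < 1e-6) { pi_hat <- newpi; break }
      pi_hat <- newpi
    }
    pi <- pi_hat
  }
  stopifnot(pi > 0, pi < 1)
  pC <- post(pi)
  flagged <- rowSums(cnt) == 0
  pC[flagged] <- pi
  nm <- nrm$normalized
  res <- data.frame(gene = rownames(cnt),
                    chip_mean = rowMeans(nm[, is_chip, drop = FALSE]),
                    input_mean = rowMeans(nm[, !is_chip, drop = FALSE]),
                    pC = pC, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "phi") <- phi
  attr(res, "pi") <- pi
  res
}
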