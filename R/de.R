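#' Quantile-normalize a log2 expression matrix
#'
#' Forces every column to share the identical sorted value vector (the
#' cross-sample mean of order statistics), preserving shape. Delegates to
#' \code{limma::normalizeQuantiles}; idempotent.
#'
#' @param m numeric probes-by-samples matrix of log2 intensities.
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  out <- limma::normalizeQuantiles(m)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-probe two-group contrast statistics
#'
#' The contrast is sh-p53 minus vector, so genes activated by p53 have
#' negative log2 fold changes. Residual variance is the classical pooled
#' two-sample estimate.
#'
#' @param m probes-by-samples matrix.
#' @param arm character vector, one of \code{"vector"}/\code{"shp53"} per
#'   column.
#' @return data.frame: \code{probe}, \code{log2fc}, \code{s2}, \code{df},
#'   plus the per-arm sample sizes as attributes \code{n1} (vector) and
#'   \code{n2} (sh-p53).
#' @export
fit_contrast <- function(m, arm) {
  stopifnot(ncol(m) == length(arm), all(arm %in% c("vector", "shp53")))
  v <- m[, arm == "vector", drop = FALSE]
  s <- m[, arm == "shp53", drop = FALSE]
  n1 <- ncol(v); n2 <- ncol(s)
  if (n1 < 2 || n2 < 2)
    stop("each arm needs >= 2 samples for a variance estimate")
  log2fc <- rowMeans(s) - rowMeans(v)
  rss <- rowSums((v - rowMeans(v))^2) + rowSums((s - rowMeans(s))^2)
  df <- n1 + n2 - 2
  out <- data.frame(probe = rownames(m), log2fc = log2fc,
                    s2 = rss / df, df = df, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-probe variances toward a prior:
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d s^2_g) / (d_0 + d).}
#' When the hyperparameters are not supplied they are estimated by moment
#' matching on the log scale: under the hierarchical model the sample
#' variances are distributed as \eqn{s_0^2 F(d, d_0)}, so
#' \eqn{Var(\log s^2) = \psi'(d/2) + \psi'(d_0/2)} determines \eqn{d_0}
#' (via the inverse trigamma) and the mean of \eqn{\log s^2} then gives
#' \eqn{s_0^2}.
#'
#' @param s2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param d0,s0sq prior degrees of freedom (may be \code{Inf}) and prior
#'   variance; estimated when \code{NULL}.
#' @return list: \code{s2_post} (moderated variances), \code{df_total}
#'   (\code{d0 + df}), \code{d0}, \code{s0sq}.
#' @export
moderate <- function(s2, df, d0 = NULL, s0sq = NULL) {
  if (is.null(d0) || is.null(s0sq)) {
    if (all(s2 <= 0))
      stop("all residual variances are zero; cannot estimate the variance ",
           "prior - supply d0 and s0sq explicitly or add replicates")
    est <- fit_fdist_moments(s2[s2 > 0], df)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s0sq)) s0sq <- est$s0sq
  }
  stopifnot(d0 >= 0, s0sq > 0)
  s2_post <- if (is.infinite(d0)) rep(s0sq, length(s2))
             else (d0 * s0sq + df * s2) / (d0 + df)
  list(s2_post = s2_post, df_total = d0 + df, d0 = d0, s0sq = s0sq)
}

# Log-moment estimator of the scaled-F hyperparameters.
fit_fdist_moments <- function(s2, df) {
  z <- log(s2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) +
                  log(df / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Solve trigamma(y) = x by Newton iteration on 1/y scale.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated t-statistics and p-values
#'
#' \eqn{t_g = \mathrm{log2fc}_g / \sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}}
#' referred to a t distribution on \code{df_total} degrees of freedom.
#' With \code{d0 = 0} this is exactly the classical pooled two-sample t.
#'
#' @param log2fc per-probe effects.
#' @param s2_post moderated variances from [moderate()].
#' @param n1,n2 per-arm sample sizes.
#' @param df_total total degrees of freedom.
#' @return data.frame with \code{t_mod} and two-sided \code{p}; zero
#'   moderated variance yields t = +/-Inf and the smallest representable p.
#' @export
moderated_t <- function(log2fc, s2_post, n1, n2, df_total) {
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p <- pmax(p, .Machine$double.xmin)
  data.frame(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via \code{stats::p.adjust(method = "BH")}.
#'
#' @param p p-values in [0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Posterior probability of differential expression
#'
#' Two-component model on the moderated t scale: under the null the
#' statistic is t-distributed on \code{df_total} df; under the alternative
#' its variance is inflated by \code{v_prior} (the scaled t density).
#' With prior odds \code{p0/(1-p0)} the posterior log-odds are
#' \deqn{O_g = \log\frac{p_0}{1-p_0} +
#'   \log\frac{f_t(t_g/\sqrt{v};\,d)/\sqrt{v}}{f_t(t_g;\,d)}}
#' and \eqn{pDE = 1/(1+e^{-O_g})}. Defaults: a prior DE fraction of 5\% and
#' an alternative-to-null variance ratio of 16 (effect SD four times the
#' statistic's null SD, the conventional empirical-Bayes upper bound).
#'
#' @param t_mod moderated t-statistics.
#' @param df_total degrees of freedom.
#' @param p0 prior probability that a probe is DE.
#' @param v_prior variance inflation of the alternative component (> 1).
#' @return pDE in [0, 1], monotone in |t|.
#' @export
de_posterior <- function(t_mod, df_total, p0 = 0.05, v_prior = 16) {
  stopifnot(p0 > 0, p0 < 1, v_prior > 1)
  lr <- stats::dt(t_mod / sqrt(v_prior), df = df_total, log = TRUE) -
    0.5 * log(v_prior) -
    stats::dt(t_mod, df = df_total, log = TRUE)
  odds <- log(p0 / (1 - p0)) + lr
  out <- stats::plogis(odds)
  out[is.infinite(t_mod)] <- 1
  out
}

#' Select differentially expressed probes or genes
#'
#' Applies the study cutoffs: BH-adjusted q below \code{q_cut} AND absolute
#' log2 fold change above \code{lfc_cut}.
#'
#' @param results data.frame with columns \code{q} and \code{log2fc} plus an
#'   identifier column (\code{gene} if present, else \code{probe}).
#' @param q_cut FDR cutoff (default 0.01).
#' @param lfc_cut absolute log2 fold-change cutoff (default 0.58).
#' @return Character vector of selected identifiers.
#' @export
select_de_genes <- function(results, q_cut = 0.01, lfc_cut = 0.58) {
  id <- if ("gene" %in% names(results)) results$gene else results$probe
  id[results$q < q_cut & abs(results$log2fc) > lfc_cut]
}

#' Full differential-expression analysis of a knockdown contrast
#'
#' Quantile-normalizes the pooled matrix, fits the sh-p53 minus vector
#' contrast, moderates variances, and computes moderated t, p, BH q and the
#' posterior probability of differential expression; optionally collapses
#' probes to genes (gene pDE = max over probes; log2fc taken from the
#' max-pDE probe).
#'
#' @param expr_vector,expr_shp53 probes-by-replicates matrices (same probes).
#' @param genome optional [genome_model()] supplying the probe-to-gene map.
#' @param p0,v_prior passed to [de_posterior()].
#' @param d0,s0sq optional variance-prior overrides for [moderate()].
#' @param normalize quantile-normalize before fitting (default TRUE).
#' @return data.frame per probe (or per gene when \code{genome} is given
#'   and \code{collapse = TRUE}): \code{probe}, \code{gene}, \code{log2fc},
#'   \code{t_mod}, \code{p}, \code{q}, \code{pDE}; hyperparameters in
#'   attribute \code{hyper}.
#' @param collapse collapse probes to genes (requires \code{genome}).
#' @export
run_de <- function(expr_vector, expr_shp53, genome = NULL,
                   p0 = 0.05, v_prior = 16, d0 = NULL, s0sq = NULL,
                   normalize = TRUE, collapse = !is.null(genome)) {
  stopifnot(nrow(expr_vector) == nrow(expr_shp53))
  m <- cbind(expr_vector, expr_shp53)
  arm <- rep(c("vector", "shp53"), c(ncol(expr_vector), ncol(expr_shp53)))
  if (normalize) m <- quantile_normalize(m)
  fc <- fit_contrast(m, arm)
  mod <- moderate(fc$s2, fc$df[1], d0 = d0, s0sq = s0sq)
  mt <- moderated_t(fc$log2fc, mod$s2_post, attr(fc, "n1"), attr(fc, "n2"),
                    mod$df_total)
  res <- data.frame(probe = fc$probe, log2fc = fc$log2fc,
                    t_mod = mt$t_mod, p = mt$p, q = bh_adjust(mt$p),
                    pDE = de_posterior(mt$t_mod, mod$df_total, p0, v_prior),
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    map <- probe_gene_map(genome)
    res$gene <- map[res$probe]
    if (collapse) res <- collapse_by_gene(res)
  }
  attr(res, "hyper") <- list(d0 = mod$d0, s0sq = mod$s0sq,
                             df_total = mod$df_total,
                             p0 = p0, v_prior = v_prior)
  res
}

probe_gene_map <- function(genome) {
  g <- genome$genes
  probes <- strsplit(as.character(g$probe_ids), ",")
  stats::setNames(rep(g$gene_id, lengths(probes)), unlist(probes))
}

#' Collapse probe-level DE results to gene level
#'
#' Gene pDE is the maximum over the gene's probes; log2fc, t and p are taken
#' from the max-pDE probe.
#'
#' @param res probe-level data.frame with a \code{gene} column.
#' @return Gene-level data.frame.
#' @export
collapse_by_gene <- function(res) {
  res <- res[!is.na(res$gene), , drop = FALSE]
  ord <- order(res$gene, -res$pDE, res$probe)
  res <- res[ord, , drop = FALSE]
  out <- res[!duplicated(res$gene), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene), c("gene", "probe", "log2fc", "t_mod", "p", "q", "pDE")]
}
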