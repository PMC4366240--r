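#' Position weight matrix
#'
#' Wraps a 4-by-L count matrix (rows A, C, G, T) with a pseudocount and
#' background base frequencies, precomputing the log-odds score matrix and
#' the per-column score extrema used for matrix-similarity-score (MSS)
#' normalization, plus the 5-column core window of highest information
#' content (the MATCH-style core).
#'
#' @param counts numeric 4-by-L non-negative matrix (or L-by-4, transposed
#'   automatically when unambiguous).
#' @param motif_id identifier.
#' @param pseudocount added to every cell before frequencies are formed.
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @return Object of class \code{pwm}.
#' @export
pwm <- function(counts, motif_id = "motif", pseudocount = 0.25,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("PWM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (ncol(counts) < 1) stop("PWM must have at least one column")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-8,
            pseudocount >= 0)
  if (any(colSums(counts) + 4 * pseudocount <= 0))
    stop("zero column after pseudocount")
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  logodds <- log2(freq / background)
  info <- colSums(freq * log2(freq / background))
  L <- ncol(counts)
  core_len <- min(5L, L)
  win_info <- vapply(seq_len(L - core_len + 1L), function(i)
    sum(info[i:(i + core_len - 1L)]), 0)
  core_start <- which.max(win_info)
  structure(list(motif_id = motif_id, counts = counts,
                 pseudocount = pseudocount, background = background,
                 logodds = logodds,
                 col_min = apply(logodds, 2, min),
                 col_max = apply(logodds, 2, max),
                 core_cols = core_start:(core_start + core_len - 1L)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$motif_id, "': ", ncol(x$counts), " columns, consensus ",
      consensus_seq(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-count base per column)
#' @param x a [pwm()].
#' @return Character scalar.
#' @export
consensus_seq <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2, which.max)], collapse = "")
}

#' The shipped p53 half-site matrix
#'
#' A synthetic decameric count matrix encoding the canonical p53
#' response-element half-site RRRCWWGYYY, with counts uniform within each
#' degeneracy class (R = A/G, W = A/T, Y = C/T). It is a declared stand-in
#' for proprietary curated matrices, intended for testing and default
#' scans.
#'
#' @param weight counts allotted per column.
#' @return A [pwm()] of length 10.
#' @export
p53_halfsite_pwm <- function(weight = 100) {
  half <- weight / 2
  col <- function(a = 0, c = 0, g = 0, t = 0) c(a, c, g, t)
  counts <- cbind(R1 = col(a = half, g = half),
                  R2 = col(a = half, g = half),
                  R3 = col(a = half, g = half),
                  C4 = col(c = weight),
                  W5 = col(a = half, t = half),
                  W6 = col(a = half, t = half),
                  G7 = col(g = weight),
                  Y8 = col(c = half, t = half),
                  Y9 = col(c = half, t = half),
                  Y10 = col(c = half, t = half))
  pwm(counts, motif_id = "p53_halfsite_synthetic")
}

seq_codes <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  code  # N and other ambiguity codes become NA (scored as background)
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), "")[[1]]),
        collapse = "")
}

scan_one_strand <- function(code, x) {
  L <- ncol(x$logodds)
  n <- length(code) - L + 1L
  if (n < 1) return(NULL)
  score <- numeric(n)
  core <- numeric(n)
  for (j in seq_len(L)) {
    col_sc <- x$logodds[, j][code[j:(j + n - 1L)]]
    col_sc[is.na(col_sc)] <- 0
    score <- score + col_sc
    if (j %in% x$core_cols) core <- core + col_sc
  }
  mss <- (score - sum(x$col_min)) / (sum(x$col_max) - sum(x$col_min))
  cmin <- sum(x$col_min[x$core_cols]); cmax <- sum(x$col_max[x$core_cols])
  core_mss <- (core - cmin) / (cmax - cmin)
  data.frame(position = seq_len(n) - 1L, score = score, mss = mss,
             core_mss = core_mss)
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands, normalizes to the matrix similarity
#' score \eqn{mss = (score - min) / (max - min) \in [0, 1]}, and reports
#' hits with \code{mss >= min_mss} whose MATCH-style core score (the best
#' 5-column high-information window) also clears \code{min_core}. N bases
#' score as background (log-odds 0).
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param x a [pwm()].
#' @param min_mss matrix score cutoff (default 0.8).
#' @param min_core core score cutoff (default 0.8; \code{NULL} disables core
#'   filtering).
#' @param sequence_id id recorded in the hits.
#' @return data.frame of hits: \code{sequence_id}, \code{position} (0-based
#'   match start on the forward strand), \code{strand}, \code{score},
#'   \code{mss}; empty for sequences shorter than the motif.
#' @export
scan_pwm <- function(seq, x, min_mss = 0.8, min_core = 0.8,
                     sequence_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  L <- ncol(x$logodds)
  empty <- data.frame(sequence_id = character(), position = integer(),
                      strand = character(), score = numeric(),
                      mss = numeric(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  fwd <- scan_one_strand(seq_codes(seq), x)
  rev <- scan_one_strand(seq_codes(revcomp(seq)), x)
  rev$position <- n - rev$position - L
  fwd$strand <- "+"
  rev$strand <- "-"
  hits <- rbind(fwd, rev)
  keep <- hits$mss >= min_mss
  if (!is.null(min_core)) keep <- keep & hits$core_mss >= min_core
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  data.frame(sequence_id = sequence_id, position = hits$position,
             strand = hits$strand, score = hits$score, mss = hits$mss,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pair half-site hits into full p53 response elements
#'
#' A full site is two same-strand half-site matches whose genomic gap
#' (second start minus first end) lies in the spacer range 0-13 bp; its
#' score is the sum of the half scores. Overlapping candidate full sites
#' are resolved greedily by descending score.
#'
#' @param seq sequence to scan.
#' @param half_pwm the decameric half-site [pwm()].
#' @param min_mss per-half matrix score cutoff.
#' @param min_core per-half core cutoff (see [scan_pwm()]).
#' @param spacer_min,spacer_max allowed spacer length in bp.
#' @param sequence_id id recorded in the hits.
#' @return data.frame: \code{sequence_id}, \code{start}, \code{end}
#'   (0-based half-open span of the full site), \code{strand},
#'   \code{spacer}, \code{score}.
#' @export
scan_full_sites <- function(seq, half_pwm, min_mss = 0.8, min_core = 0.8,
                            spacer_min = 0L, spacer_max = 13L,
                            sequence_id = "seq") {
  stopifnot(spacer_min >= 0, spacer_max >= spacer_min)
  halves <- scan_pwm(seq, half_pwm, min_mss, min_core, sequence_id)
  L <- ncol(half_pwm$logodds)
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(halves) < 2) return(empty)
  cand <- list()
  for (st in c("+", "-")) {
    h <- halves[halves$strand == st, , drop = FALSE]
    h <- h[order(h$position), , drop = FALSE]
    if (nrow(h) < 2) next
    for (i in seq_len(nrow(h) - 1)) {
      for (j in (i + 1):nrow(h)) {
        gap <- h$position[j] - (h$position[i] + L)
        if (gap > spacer_max) break
        if (gap >= spacer_min)
          cand[[length(cand) + 1L]] <- data.frame(
            sequence_id = sequence_id, start = h$position[i],
            end = h$position[j] + L, strand = st, spacer = gap,
            score = h$score[i] + h$score[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start, cand$strand), , drop = FALSE]
  taken <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { taken[1] <- TRUE; next }
    acc <- cand[taken, , drop = FALSE]
    if (!any(cand$start[i] < acc$end & acc$start < cand$end[i]))
      taken[i] <- TRUE
  }
  out <- cand[taken, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Positional histogram of motif hits around anchors
#'
#' Each hit's start is converted into a signed, strand-aware offset from its
#' sequence's anchor (negative = upstream); offsets in the half-open window
#' [-window, +window) are counted in fixed bins and frequencies are counts
#' divided by the number of anchored regions.
#'
#' @param hits data.frame from [scan_pwm()] (columns \code{sequence_id},
#'   \code{position}).
#' @param anchors data.frame with \code{sequence_id}, \code{anchor}
#'   (position in the same coordinates as the hits) and \code{strand} of
#'   the anchored gene.
#' @param window half-width in bp (default 1000).
#' @param bin bin width in bp (default 50); \code{2 * window} must be a
#'   multiple of \code{bin}.
#' @return data.frame: \code{bin_start}, \code{bin_end} (signed offsets),
#'   \code{count}, \code{frequency}.
#' @export
positional_histogram <- function(hits, anchors, window = 1000L, bin = 50L) {
  if ((2 * window) %% bin != 0)
    stop("window is not divisible by the bin width")
  n_bins <- as.integer(2 * window / bin)
  breaks <- seq(-window, window, by = bin)
  counts <- integer(n_bins)
  if (nrow(hits) > 0) {
    idx <- match(hits$sequence_id, anchors$sequence_id)
    if (any(is.na(idx))) stop("hit sequence_id missing from anchors")
    off <- ifelse(anchors$strand[idx] == "-",
                  anchors$anchor[idx] - hits$position,
                  hits$position - anchors$anchor[idx])
    off <- off[off >= -window & off < window]
    if (length(off) > 0) {
      b <- floor((off + window) / bin) + 1L
      tab <- tabulate(b, nbins = n_bins)
      counts <- counts + tab
    }
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts, frequency = counts / nrow(anchors))
}

#' Promoter motif enrichment z-test
#'
#' Compares the mean best-hit matrix similarity score of a foreground
#' promoter set against an equal-length background set:
#' z = (mean_fg - mean_bg) / SE with a two-sided normal p-value.
#'
#' @param fg,bg character vectors of promoter sequences; all sequences must
#'   share one length.
#' @param x a [pwm()].
#' @return list: \code{z}, \code{p}, \code{mean_fg}, \code{mean_bg}.
#' @export
promoter_enrichment_ztest <- function(fg, bg, x) {
  if (length(unique(nchar(c(fg, bg)))) != 1)
    stop("foreground and background promoters must have equal length")
  best <- function(seqs) vapply(seqs, function(s) {
    h <- rbind(scan_one_strand(seq_codes(s), x),
               scan_one_strand(seq_codes(revcomp(s)), x))
    max(h$mss)
  }, 0, USE.NAMES = FALSE)
  a <- best(fg); b <- best(bg)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  z <- (mean(a) - mean(b)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)),
       mean_fg = mean(a), mean_bg = mean(b))
}

#' Helpers for motif-planting simulations
#'
#' \code{random_dna} draws a uniform-background sequence; \code{plant_motif}
#' overwrites a stretch of a sequence with a motif instance at a 0-based
#' offset.
#'
#' @param n sequence length.
#' @return \code{random_dna}: a character scalar.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @rdname random_dna
#' @param seq sequence to modify.
#' @param motif instance to plant.
#' @param at 0-based offset.
#' @export
plant_motif <- function(seq, motif, at) {
  stopifnot(at >= 0, at + nchar(motif) <= nchar(seq))
  paste0(substr(seq, 1, at), motif,
         substr(seq, at + nchar(motif) + 1, nchar(seq)))
}
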