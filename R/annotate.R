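#' Classify peaks by genomic feature
#'
#' Each peak is anchored at its midpoint and assigned exactly one category,
#' tested in priority order: core promoter (TSS offset in [-3000, +2000]),
#' downstream extremity (TES offset in [-2000, +3000]), exon, intron,
#' distal (within 50 kb of a TSS), intergenic (beyond 50 kb of every gene).
#' Offsets are signed in the direction of transcription (negative =
#' upstream) and computed against the nearest gene by TSS distance, ties
#' broken by the lexicographically smaller gene id. Exon/intron containment
#' is tested against any gene, so a peak inside one gene's intron is not
#' called distal to a neighbour.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genome a [genome_model()].
#' @return data.frame with one row per peak: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{category}, \code{gene} (NA for
#'   intergenic), \code{offset} (bp from the assigned gene's TSS).
#' @export
classify_peaks <- function(peaks, genome) {
  genes <- genome$genes
  if (nrow(genes) == 0) stop("genome model has no genes")
  n <- length(peaks)
  mid <- floor((start0(peaks) + end0(peaks)) / 2)
  pchrom <- as.character(GenomicRanges::seqnames(peaks))

  body_start <- pmin(genes$tss, genes$tes)
  body_end <- pmax(genes$tss, genes$tes)
  exon_list <- parse_exons(genes)

  category <- character(n)
  gene <- rep(NA_character_, n)
  offset <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    on_chr <- which(genes$chrom == pchrom[k])
    if (length(on_chr) == 0) { category[k] <- "intergenic"; next }
    d <- abs(mid[k] - genes$tss[on_chr])
    near <- on_chr[d == min(d)]
    g <- near[order(genes$gene_id[near])][1]
    off <- signed_offset(mid[k], genes$tss[g], genes$strand[g])
    off_tes <- signed_offset(mid[k], genes$tes[g], genes$strand[g])
    gene[k] <- genes$gene_id[g]
    offset[k] <- off
    if (off >= -3000 && off <= 2000) {
      category[k] <- "core_promoter"
    } else if (off_tes >= -2000 && off_tes <= 3000) {
      category[k] <- "downstream_extremity"
    } else {
      inside <- on_chr[body_start[on_chr] <= mid[k] & mid[k] <= body_end[on_chr]]
      in_exon <- inside[vapply(inside, function(i) {
        ex <- exon_list[[i]]
        any(ex$start <= mid[k] & mid[k] < ex$end)
      }, FALSE)]
      if (length(in_exon) > 0) {
        g2 <- in_exon[order(genes$gene_id[in_exon])][1]
        category[k] <- "exon"
        gene[k] <- genes$gene_id[g2]
        offset[k] <- signed_offset(mid[k], genes$tss[g2], genes$strand[g2])
      } else if (length(inside) > 0) {
        g2 <- inside[order(genes$gene_id[inside])][1]
        category[k] <- "intron"
        gene[k] <- genes$gene_id[g2]
        offset[k] <- signed_offset(mid[k], genes$tss[g2], genes$strand[g2])
      } else if (min(d) <= 50000) {
        category[k] <- "distal"
      } else {
        category[k] <- "intergenic"
        gene[k] <- NA_character_
        offset[k] <- NA_real_
      }
    }
  }
  data.frame(chrom = pchrom, start = start0(peaks), end = end0(peaks),
             category = category, gene = gene, offset = offset,
             stringsAsFactors = FALSE)
}

signed_offset <- function(pos, anchor, strand) {
  if (strand == "+") pos - anchor else anchor - pos
}

parse_exons <- function(genes) {
  lapply(seq_len(nrow(genes)), function(i) {
    s <- suppressWarnings(as.numeric(strsplit(
      as.character(genes$exon_starts[i]), ",")[[1]]))
    e <- suppressWarnings(as.numeric(strsplit(
      as.character(genes$exon_ends[i]), ",")[[1]]))
    s <- s[!is.na(s)]; e <- e[!is.na(e)]
    data.frame(start = s, end = e)
  })
}

#' Partition peaks by CpG-island overlap
#'
#' A peak sharing at least one base with a CGI joins the CGI peak set; the
#' remainder form the non-CGI set. The partition is exhaustive and disjoint.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param cgis \code{GRanges} of CpG islands.
#' @return list with \code{cgi_peaks}, \code{non_cgi_peaks} (both
#'   \code{GRanges}) and \code{cgi_fraction}.
#' @export
partition_by_cgi <- function(peaks, cgis) {
  if (length(peaks) == 0)
    return(list(cgi_peaks = peaks, non_cgi_peaks = peaks,
                cgi_fraction = NaN))
  is_cgi <- GenomicRanges::countOverlaps(peaks, cgis,
                                         ignore.strand = TRUE) > 0
  list(cgi_peaks = peaks[is_cgi],
       non_cgi_peaks = peaks[!is_cgi],
       cgi_fraction = mean(is_cgi))
}

#' Summarise the peak-width distribution
#'
#' @param peaks \code{GRanges}.
#' @param binwidth histogram bin width in bp.
#' @return list with \code{n}, \code{median}, \code{q25}, \code{q75},
#'   \code{breaks} and \code{counts}; all-NA summary for an empty set.
#' @export
peak_width_distribution <- function(peaks, binwidth = 100) {
  if (length(peaks) == 0)
    return(list(n = 0L, median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                breaks = numeric(0), counts = integer(0)))
  w <- end0(peaks) - start0(peaks)
  breaks <- seq(0, binwidth * ceiling(max(w) / binwidth), by = binwidth)
  h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  list(n = length(w), median = stats::median(w),
       q25 = unname(stats::quantile(w, 0.25)),
       q75 = unname(stats::quantile(w, 0.75)),
       breaks = breaks, counts = h$counts)
}

#' Core-promoter subset of a peak classification
#'
#' @param classification data.frame from [classify_peaks()].
#' @return The rows with \code{category == "core_promoter"}.
#' @export
promoter_subset <- function(classification) {
  classification[classification$category == "core_promoter", , drop = FALSE]
}

#' Annotate peaks: feature classes plus CGI partition
#'
#' Convenience wrapper combining [classify_peaks()] and [partition_by_cgi()].
#'
#' @inheritParams classify_peaks
#' @return list with \code{table} (classification data.frame plus a
#'   \code{cgi} flag column) and \code{summary} (category proportions and
#'   \code{cgi_fraction}).
#' @export
annotate_peaks <- function(peaks, genome) {
  cls <- classify_peaks(peaks, genome)
  part <- partition_by_cgi(peaks, genome$cgis)
  cls$cgi <- GenomicRanges::countOverlaps(peaks, genome$cgis,
                                          ignore.strand = TRUE) > 0
  cats <- c("core_promoter", "downstream_extremity", "exon", "intron",
            "distal", "intergenic")
  prop <- vapply(cats, function(ct) mean(cls$category == ct), 0)
  list(table = cls,
       summary = list(category_proportions = prop,
                      cgi_fraction = part$cgi_fraction))
}
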