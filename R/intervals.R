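#' Construct genomic intervals from 0-based half-open coordinates
#'
#' The package's interchange convention is the BED one: 0-based start,
#' exclusive end. Internally intervals are held as \link[GenomicRanges]{GRanges}
#' (1-based, closed); this constructor performs the conversion and validates
#' the invariants (start >= 0, end > start, non-empty chromosome).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open span.
#' @param strand strand codes among \code{"+"}, \code{"-"}, \code{"*"}.
#' @return A \code{GRanges} of the same length as the inputs.
#' @export
gi <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chromosome names must be non-empty")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval coordinates must be finite")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

#' 0-based starts and exclusive ends of a GRanges
#'
#' Inverse of the coordinate shift applied by [gi()].
#' @param gr a \code{GRanges}.
#' @return Integer vector.
#' @export
start0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname start0
#' @export
end0 <- function(gr) GenomicRanges::end(gr)

#' Test whether two intervals share at least one base
#'
#' Overlap requires the same chromosome and a non-empty intersection of the
#' half-open spans; strand is ignored (p53 binding is not strand-resolved).
#' Abutting intervals do not overlap.
#'
#' @param a,b \code{GRanges}, typically of length 1; vectorised elementwise
#'   when both have equal length.
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1 || length(b) == 1)
  as.logical(IRanges::poverlaps(a, b, ignore.strand = TRUE))
}

#' Merge overlapping intervals into their disjoint union
#'
#' Collapses transitive overlap chains into single intervals; the result is
#' sorted, disjoint, and covers exactly the union of the input bases (one
#' interval per maximal covered run, so exactly abutting intervals coalesce).
#'
#' @param gr a \code{GRanges} (possibly empty).
#' @return A sorted, disjoint \code{GRanges}.
#' @export
merge_intervals <- function(gr) {
  if (length(gr) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Build a peak set
#'
#' A peak is an interval plus its peak-caller score and its provenance
#' (condition label and replicate id), carried as metadata columns.
#'
#' @param gr interval spans (\code{GRanges}, e.g. from [gi()] or [read_bed()]).
#' @param score non-negative numeric peak scores.
#' @param condition condition label (e.g. Grow/acDDR/RIS/pApo).
#' @param replicate integer replicate id, >= 1.
#' @return \code{GRanges} with mcols \code{score}, \code{condition},
#'   \code{replicate}.
#' @export
peak_set <- function(gr, score = 0, condition = "cond", replicate = 1L) {
  score <- rep_len(as.numeric(score), length(gr))
  replicate <- rep_len(as.integer(replicate), length(gr))
  if (any(score < 0)) stop("peak scores must be >= 0")
  if (any(replicate < 1L)) stop("replicate ids must be >= 1")
  S4Vectors::mcols(gr)$score <- score
  S4Vectors::mcols(gr)$condition <- rep_len(as.character(condition), length(gr))
  S4Vectors::mcols(gr)$replicate <- replicate
  gr
}

#' Assemble a genome model
#'
#' Bundles the gene records, CpG-island intervals and chromosome sizes that
#' form the coordinate frame for annotation, binning and simulation.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{strand} (+/-), \code{tss}, \code{tes} (0-based positions of the
#'   first/last transcribed base), \code{exon_starts}, \code{exon_ends}
#'   (comma-separated 0-based half-open coordinates), and optionally
#'   \code{probe_ids} (comma-separated).
#' @param cgis \code{GRanges} of CpG islands.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return An object of class \code{genome_model}.
#' @export
genome_model <- function(genes, cgis, chrom_sizes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "tss", "tes") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  bad <- ifelse(genes$strand == "+", genes$tss >= genes$tes, genes$tss <= genes$tes)
  if (any(bad)) stop("tss/tes order inconsistent with strand for: ",
                     paste(utils::head(genes$gene_id[bad]), collapse = ", "))
  if (is.null(genes$probe_ids)) genes$probe_ids <- genes$gene_id
  sz <- chrom_sizes[genes$chrom]
  if (any(is.na(sz)) || any(pmax(genes$tss, genes$tes) >= sz))
    stop("gene coordinates exceed chromosome sizes")
  if (length(cgis) > 0) {
    csz <- chrom_sizes[as.character(GenomicRanges::seqnames(cgis))]
    if (any(is.na(csz)) || any(end0(cgis) > csz))
      stop("CGI coordinates exceed chromosome sizes")
  }
  structure(list(genes = genes, cgis = cgis, chrom_sizes = chrom_sizes),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$genes), "genes,", length(x$cgis), "CGIs,",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

# TSS window of each gene for TSS-local read counting: [tss-up, tss+down)
# in transcription direction, as 0-based half-open genomic coordinates.
tss_windows <- function(genes, upstream = 50L, downstream = 1500L) {
  plus <- genes$strand == "+"
  w_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  w_end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(w_start, 0), end = w_end,
             stringsAsFactors = FALSE)
}
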