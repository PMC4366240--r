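#' Read and write BED3+ files
#'
#' Thin wrappers around \pkg{rtracklayer} that keep the package's 0-based
#' half-open convention on disk and return \code{GRanges} in memory.
#' Optional columns (name, score, strand) are preserved when present and
#' tolerated when missing.
#'
#' @param path file path.
#' @return \code{read_bed}: a \code{GRanges}, with \code{name}/\code{score}
#'   metadata columns when the file carries them.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param gr \code{GRanges} to write; mcols \code{name} and \code{score} are
#'   emitted as BED columns 4-5 when present.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write tab-separated gene-model tables
#'
#' Columns: \code{gene_id, chrom, strand, txStart, txEnd, exonStarts,
#' exonEnds[, probe_ids]} with txStart/txEnd 0-based half-open (UCSC style).
#' TSS/TES are derived by strand: for \code{+} genes TSS = txStart and
#' TES = txEnd - 1; for \code{-} genes TSS = txEnd - 1 and TES = txStart,
#' so TSS/TES are 0-based positions of the first/last transcribed base.
#'
#' @param path file path.
#' @return \code{read_gene_table}: a gene data.frame as used by
#'   [genome_model()].
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  plus <- tab$strand == "+"
  tab$tss <- ifelse(plus, tab$txStart, tab$txEnd - 1L)
  tab$tes <- ifelse(plus, tab$txEnd - 1L, tab$txStart)
  if (is.null(tab$exonStarts)) tab$exonStarts <- as.character(tab$txStart)
  if (is.null(tab$exonEnds)) tab$exonEnds <- as.character(tab$txEnd)
  tab$exon_starts <- tab$exonStarts
  tab$exon_ends <- tab$exonEnds
  if (!is.null(tab$probe_ids)) tab$probe_ids <- as.character(tab$probe_ids)
  tab[c("gene_id", "chrom", "strand", "tss", "tes",
        "exon_starts", "exon_ends",
        intersect("probe_ids", names(tab)))]
}

#' @rdname read_gene_table
#' @param genes gene data.frame (see [genome_model()]).
#' @export
write_gene_table <- function(genes, path) {
  plus <- genes$strand == "+"
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    txStart = ifelse(plus, genes$tss, genes$tes),
                    txEnd = ifelse(plus, genes$tes + 1L, genes$tss + 1L),
                    exonStarts = genes$exon_starts,
                    exonEnds = genes$exon_ends,
                    stringsAsFactors = FALSE)
  if (!is.null(genes$probe_ids)) out$probe_ids <- genes$probe_ids
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position-weight count matrix
#'
#' Format: a header line \code{>motif_id} followed by four whitespace-separated
#' rows of non-negative counts in A, C, G, T order. Several motifs may be
#' concatenated in one file.
#'
#' @param path file path.
#' @return A list of [pwm()] objects (length one for single-motif files).
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("PWM file must start with a '>motif_id' header")
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4)
      stop("each PWM needs exactly 4 count rows (A, C, G, T)")
    counts <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    pwm(counts, motif_id = sub("^>\\s*", "", lines[heads[i]]))
  })
  names(out) <- vapply(out, function(p) p$motif_id, "")
  out
}

#' @rdname read_pwm
#' @param x a [pwm()] object.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$motif_id), con)
  utils::write.table(x$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Wrapper around \code{Biostrings::readDNAStringSet} for the motif-scanning
#' functions, which operate on plain character sequences.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Read and write genes-by-samples tables (counts or log2 intensities)
#'
#' Plain TSV with row identifiers in the first column.
#'
#' @param path file path.
#' @return \code{read_matrix_tsv}: a numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with rownames.
#' @param id_col name for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  out <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
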