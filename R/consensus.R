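#' Cluster one condition's replicate peaks by overlap
#'
#' Peaks from all replicates of a condition are clustered by single-linkage
#' overlap (transitive chains collapse into one cluster). A cluster counts as
#' replicated when its members come from at least two distinct replicate ids;
#' multiple peaks from one replicate do not make a cluster replicated.
#'
#' @param peaks \code{GRanges} with mcols \code{condition}, \code{replicate},
#'   \code{score} (see [peak_set()]); all peaks must carry \code{condition}.
#' @param condition the condition the peaks belong to (checked).
#' @return \code{GRanges} of cluster spans (the merged union of members) with
#'   mcols: \code{condition}, \code{n_members}, \code{support} (number of
#'   distinct replicates), \code{replicated} (support >= 2), \code{score}
#'   (max member score) and \code{members} (IntegerList of member indices
#'   into \code{peaks}).
#' @export
cluster_within_condition <- function(peaks, condition = NULL) {
  if (length(peaks) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      condition = character(), n_members = integer(), support = integer(),
      replicated = logical(), score = numeric(),
      members = IRanges::IntegerList())
    return(gr)
  }
  cond <- unique(S4Vectors::mcols(peaks)$condition)
  if (length(cond) != 1)
    stop("peaks from several conditions passed to cluster_within_condition")
  if (!is.null(condition) && cond != condition)
    stop("peaks carry condition '", cond, "', expected '", condition, "'")
  red <- GenomicRanges::reduce(peaks, ignore.strand = TRUE,
                               with.revmap = TRUE)
  members <- S4Vectors::mcols(red)$revmap
  rep_ids <- S4Vectors::mcols(peaks)$replicate
  scores <- S4Vectors::mcols(peaks)$score
  support <- vapply(members, function(i) length(unique(rep_ids[i])), 0L)
  S4Vectors::mcols(red) <- S4Vectors::DataFrame(
    condition = cond,
    n_members = lengths(members),
    support = support,
    replicated = support >= 2L,
    score = vapply(members, function(i) max(scores[i]), 0),
    members = members)
  red
}

#' Rescue singleton peak clusters by cross-condition support
#'
#' A singleton cluster (replicate support 1) of condition \code{c} enters the
#' high-confidence set when either
#' (i) it overlaps at least one peak in each of two or more conditions other
#' than \code{c}, or
#' (ii) some single other condition has peaks overlapping it in at least two
#' distinct replicates.
#'
#' @param singletons \code{GRanges} of singleton cluster spans with mcol
#'   \code{condition}.
#' @param all_peaks \code{GRanges} of every condition's replicate peaks.
#' @param strict when \code{TRUE}, only partner peaks that are themselves part
#'   of a replicated cluster in their own condition can support rule (i) or
#'   (ii); the default permissive reading counts any peak.
#' @return The input with added mcols \code{rescued}, \code{rule}
#'   (\code{"i"}, \code{"ii"}, \code{"i+ii"} or \code{""}).
#' @export
rescue_singletons <- function(singletons, all_peaks, strict = FALSE) {
  conds <- unique(S4Vectors::mcols(all_peaks)$condition)
  if (length(singletons) > 0 && length(conds) < 3)
    warning("fewer than 2 other conditions available: rescue rule (i) cannot fire")
  if (strict && length(all_peaks) > 0) {
    keep <- rep(FALSE, length(all_peaks))
    pcond <- S4Vectors::mcols(all_peaks)$condition
    for (cc in conds) {
      idx <- which(pcond == cc)
      cl <- cluster_within_condition(all_peaks[idx])
      rep_members <- unlist(S4Vectors::mcols(cl)$members[
        S4Vectors::mcols(cl)$replicated])
      keep[idx[rep_members]] <- TRUE
    }
    all_peaks <- all_peaks[keep]
  }
  rescued <- logical(length(singletons))
  rule <- character(length(singletons))
  if (length(singletons) == 0) {
    S4Vectors::mcols(singletons)$rescued <- rescued
    S4Vectors::mcols(singletons)$rule <- rule
    return(singletons)
  }
  hits <- GenomicRanges::findOverlaps(singletons, all_peaks,
                                      ignore.strand = TRUE)
  pcond <- S4Vectors::mcols(all_peaks)$condition
  prep <- S4Vectors::mcols(all_peaks)$replicate
  scond <- S4Vectors::mcols(singletons)$condition
  for (k in seq_along(singletons)) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]
    j <- j[pcond[j] != scond[k]]
    if (length(j) == 0) next
    rule_i <- length(unique(pcond[j])) >= 2
    per_cond_reps <- tapply(prep[j], pcond[j],
                            function(r) length(unique(r)))
    rule_ii <- any(per_cond_reps >= 2)
    rescued[k] <- rule_i || rule_ii
    rule[k] <- paste(c(if (rule_i) "i", if (rule_ii) "ii"), collapse = "+")
  }
  S4Vectors::mcols(singletons)$rescued <- rescued
  S4Vectors::mcols(singletons)$rule <- rule
  singletons
}

#' Build high-confidence peak sets for every condition
#'
#' Per condition, replicate peaks are clustered by overlap; clusters supported
#' by two or more replicates are kept, singleton clusters are offered for
#' cross-condition rescue ([rescue_singletons()]), and the surviving spans are
#' merged into the final, disjoint high-confidence (HC) peak set.
#'
#' @param peaks \code{GRanges} of all conditions' replicate peaks (mcols
#'   \code{condition}, \code{replicate}, \code{score}).
#' @param strict_rescue passed to [rescue_singletons()] as \code{strict}.
#' @return list with
#'   \describe{
#'     \item{hc}{named list of \code{GRanges}, one HC set per condition, with
#'       mcol \code{provenance} (\code{"replicated"}, \code{"rescued"} or
#'       \code{"replicated+rescued"}).}
#'     \item{audit}{data.frame of every cluster with its span, support, the
#'       rule that admitted it (or \code{"dropped"}).}
#'   }
#' @export
build_hc_peakset <- function(peaks, strict_rescue = FALSE) {
  conds <- unique(S4Vectors::mcols(peaks)$condition)
  pcond <- S4Vectors::mcols(peaks)$condition
  clusters <- lapply(conds, function(cc)
    cluster_within_condition(peaks[pcond == cc]))
  names(clusters) <- conds
  audit <- list()
  hc <- list()
  for (cc in conds) {
    cl <- clusters[[cc]]
    repl <- S4Vectors::mcols(cl)$replicated
    singles <- cl[!repl]
    singles <- rescue_singletons(singles, peaks, strict = strict_rescue)
    status <- character(length(cl))
    status[repl] <- "replicated"
    status[!repl] <- ifelse(S4Vectors::mcols(singles)$rescued,
                            paste0("rescued_", S4Vectors::mcols(singles)$rule),
                            "dropped")
    audit[[cc]] <- data.frame(
      condition = cc,
      chrom = as.character(GenomicRanges::seqnames(cl)),
      start = start0(cl), end = end0(cl),
      support = S4Vectors::mcols(cl)$support,
      n_members = S4Vectors::mcols(cl)$n_members,
      score = S4Vectors::mcols(cl)$score,
      status = status,
      stringsAsFactors = FALSE)
    keep_spans <- c(GenomicRanges::granges(cl[repl]),
                    GenomicRanges::granges(singles[
                      S4Vectors::mcols(singles)$rescued]))
    src <- c(rep("replicated", sum(repl)),
             rep("rescued", sum(S4Vectors::mcols(singles)$rescued)))
    merged <- GenomicRanges::reduce(keep_spans, ignore.strand = TRUE,
                                    with.revmap = TRUE)
    prov <- vapply(S4Vectors::mcols(merged)$revmap, function(i)
      paste(sort(unique(src[i])), collapse = "+"), "")
    merged <- GenomicRanges::granges(merged)
    S4Vectors::mcols(merged)$provenance <- prov
    hc[[cc]] <- merged
  }
  list(hc = hc, audit = do.call(rbind, audit))
}
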