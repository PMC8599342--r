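#' Classify two peak sets into state-specific and shared groups
#'
#' A peak from set A is A-specific ("open in A but closed in B") iff it
#' overlaps no peak of B by at least `min_overlap` bases; symmetrically
#' for B. Overlapping pairs form the shared group. The rule is peak-set
#' membership, not a quantitative signal ratio. Intervals are half-open
#' at the BED level, so peaks that merely touch do not overlap.
#'
#' @param peaks_a,peaks_b Peak `GRanges` (each internally disjoint; they
#'   are sorted internally).
#' @param min_overlap Minimum overlap in bases to count as shared.
#' @param min_frac Optional reciprocal overlap fraction: a pair is shared
#'   only if the overlap covers at least this fraction of *both* peaks.
#' @return A `peak_classification` list: `A_specific`, `B_specific`,
#'   `shared_a`, `shared_b` (`GRanges`), and `pairs` (data.frame of
#'   overlapping A/B indices).
#' @export
classify_peaks <- function(peaks_a, peaks_b, min_overlap = 1L,
                           min_frac = NULL) {
  for (p in list(peaks_a, peaks_b)) {
    if (length(p) && any(GenomicRanges::width(p) < 1L)) {
      stop_usage("malformed peak intervals")
    }
  }
  if (min_overlap < 1L) stop_usage("min_overlap must be >= 1")
  peaks_a <- GenomicRanges::sort(peaks_a, ignore.strand = TRUE)
  peaks_b <- GenomicRanges::sort(peaks_b, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(peaks_a, peaks_b,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (!is.null(min_frac)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      peaks_a[S4Vectors::queryHits(hits)], peaks_b[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    keep <- ov >= min_frac * GenomicRanges::width(peaks_a[S4Vectors::queryHits(hits)]) &
      ov >= min_frac * GenomicRanges::width(peaks_b[S4Vectors::subjectHits(hits)])
    hits <- hits[keep]
  }
  qa <- unique(S4Vectors::queryHits(hits))
  qb <- unique(S4Vectors::subjectHits(hits))
  structure(list(
    A_specific = peaks_a[setdiff(seq_along(peaks_a), qa)],
    B_specific = peaks_b[setdiff(seq_along(peaks_b), qb)],
    shared_a = peaks_a[qa],
    shared_b = peaks_b[qb],
    pairs = data.frame(a = S4Vectors::queryHits(hits),
                       b = S4Vectors::subjectHits(hits))
  ), class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  cat("peak_classification: ", length(x$A_specific), " A-specific, ",
      length(x$B_specific), " B-specific, ", nrow(x$pairs),
      " shared pair(s)\n", sep = "")
  invisible(x)
}

#' Link peaks to genes by TSS proximity
#'
#' Gene and peak are linked iff the TSS base lies within `window` bases of
#' the peak: distance 0 when the TSS falls inside the peak, otherwise the
#' number of bases from the TSS to the nearest peak base, with the window
#' bound inclusive ("within 10 kb" read inclusively). A peak may link to
#' many genes and a gene to many peaks.
#'
#' @param peaks A peak `GRanges`.
#' @param tss A width-1 `GRanges` with a `gene` metadata column.
#' @param window Maximum distance in bases.
#' @return A data.frame of links: `gene`, `peak` (name or index), `chrom`,
#'   `peak_start`, `peak_end` (0-based half-open), `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, tss, window = 10000L) {
  if (window < 0L) stop_usage("window must be >= 0")
  if (is.null(tss$gene)) stop_usage("tss needs a 'gene' metadata column")
  if (!length(peaks) || !length(tss)) {
    return(data.frame(gene = character(0), peak = character(0),
                      chrom = character(0), peak_start = integer(0),
                      peak_end = integer(0), distance = integer(0)))
  }
  padded <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(GenomicRanges::start(peaks) - window, 1L),
                     GenomicRanges::end(peaks) + window))
  hits <- GenomicRanges::findOverlaps(tss, padded, ignore.strand = TRUE)
  ti <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(tss)[ti]
  d <- pmax(GenomicRanges::start(peaks)[pi] - pos,
            pos - GenomicRanges::end(peaks)[pi], 0L)
  keep <- d <= window
  ti <- ti[keep]; pi <- pi[keep]; d <- d[keep]
  peak_id <- if (!is.null(peaks$name)) peaks$name[pi] else as.character(pi)
  out <- data.frame(gene = tss$gene[ti],
                    peak = peak_id,
                    chrom = as.character(GenomicRanges::seqnames(peaks))[pi],
                    peak_start = GenomicRanges::start(peaks)[pi] - 1L,
                    peak_end = GenomicRanges::end(peaks)[pi],
                    distance = as.integer(d))
  out[order(out$gene, out$chrom, out$peak_start), , drop = FALSE]
}
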