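#' Remove low-mapping-quality tags
#'
#' Keeps tags with `mapq >= min_mapq`, the semantics of
#' `samtools view -q` (the boundary value is retained). Order is
#' preserved; empty input passes through.
#'
#' @param tags A `GRanges` with a `mapq` metadata column.
#' @param min_mapq Minimum mapping quality kept.
#' @return The filtered `GRanges`.
#' @export
filter_low_quality <- function(tags, min_mapq = 35L) {
  if (is.null(tags$mapq)) stop_usage("tags need a 'mapq' metadata column")
  tags[tags$mapq >= min_mapq]
}

#' Remove mitochondrial tags
#'
#' Drops tags whose chromosome name is in `mito_names`; filtering is
#' name-based (the mitochondrial chromosome is `chrM` by convention).
#' Order is preserved.
#'
#' @param tags A `GRanges`.
#' @param mito_names Chromosome names treated as mitochondrial.
#' @return The filtered `GRanges`.
#' @export
remove_mitochondrial <- function(tags, mito_names = "chrM") {
  tags[!(as.character(GenomicRanges::seqnames(tags)) %in% mito_names)]
}

#' Deduplicate tags by genomic location and strand
#'
#' Keeps the first occurrence of each `(chrom, start, end, strand)` key:
#' tags at the same position on opposite strands are distinct. Idempotent.
#'
#' @param tags A `GRanges`.
#' @return The deduplicated `GRanges`.
#' @export
deduplicate <- function(tags) {
  key <- paste(as.character(GenomicRanges::seqnames(tags)),
               GenomicRanges::start(tags), GenomicRanges::end(tags),
               as.character(GenomicRanges::strand(tags)), sep = "\r")
  tags[!duplicated(key)]
}

#' Merge replicate tag sets
#'
#' Concatenates the replicates and coordinate-sorts the result. No
#' re-deduplication happens across replicates: deduplication is a
#' per-replicate step, and identical positions in different biological
#' replicates are signal, not artifacts.
#'
#' @param replicates A list of tag `GRanges`.
#' @return A coordinate-sorted `GRanges`.
#' @export
merge_replicates <- function(replicates) {
  if (!is.list(replicates) || !length(replicates)) {
    stop_usage("merge_replicates needs a non-empty list of tag sets")
  }
  merged <- do.call(c, unname(replicates))
  GenomicRanges::sort(merged, ignore.strand = TRUE)
}

#' Apply the full per-replicate filter chain
#'
#' MAPQ filter, mitochondrial removal, then deduplication, in the order
#' the processing is described; the two removal filters commute, and
#' deduplication is idempotent.
#'
#' @param tags A `GRanges` with `mapq`.
#' @param min_mapq Minimum mapping quality kept.
#' @param mito_names Mitochondrial chromosome names.
#' @return The filtered `GRanges`.
#' @export
filter_tags <- function(tags, min_mapq = 35L, mito_names = "chrM") {
  deduplicate(remove_mitochondrial(filter_low_quality(tags, min_mapq),
                                   mito_names))
}

#' Build a scaled coverage track
#'
#' Per-base tag coverage with the reads-per-ten-million scale factor
#' `10^7 / total_unique_reads`. The raw integer coverage is stored; the
#' scale is applied when values are exported or integrated, so the track's
#' genome-wide integral is exactly `scale_factor` times the summed tag
#' lengths. Tags are assumed to be already filtered and deduplicated.
#'
#' @param tags A `GRanges` (with seqlengths set, so uncovered chromosome
#'   tails are kept as zeros).
#' @return An object of class `coverage_track`: `cov` (per-chromosome
#'   `Rle` of raw counts), `scale_factor`, `total_unique_reads`,
#'   `mean_tag_length`.
#' @export
make_coverage <- function(tags) {
  total <- length(tags)
  if (total == 0L) {
    warning("zero tags: coverage track is empty and scale factor undefined")
    return(structure(list(cov = GenomicRanges::coverage(tags),
                          scale_factor = NA_real_,
                          total_unique_reads = 0L,
                          mean_tag_length = NA_real_),
                     class = "coverage_track"))
  }
  structure(list(cov = GenomicRanges::coverage(tags),
                 scale_factor = 1e7 / total,
                 total_unique_reads = total,
                 mean_tag_length = sum(as.numeric(GenomicRanges::width(tags))) / total),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: ", length(x$cov), " chromosome(s), ",
      x$total_unique_reads, " tags, scale ", signif(x$scale_factor, 6),
      "\n", sep = "")
  invisible(x)
}

#' Genome-wide integral of a scaled coverage track
#'
#' @param track A [make_coverage()] track.
#' @return `scale_factor` x total covered bases (tag-length mass).
#' @export
track_integral <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  mass <- sum(vapply(track$cov, function(r) sum(as.numeric(r)), numeric(1)))
  if (is.na(track$scale_factor)) return(0)
  mass * track$scale_factor
}

#' Average several coverage tracks at the signal level
#'
#' Alternative to read-level replicate merging: the per-base mean of the
#' scaled tracks, flagged as a mean track in its metadata.
#'
#' @param tracks List of [make_coverage()] tracks over the same genome.
#' @return A `coverage_track` whose `cov` holds the (numeric) mean scaled
#'   values, with `scale_factor = 1` and `is_mean = TRUE`.
#' @export
mean_coverage <- function(tracks) {
  if (!length(tracks)) stop_usage("need at least one track")
  scaled <- lapply(tracks, function(t) t$cov * t$scale_factor)
  acc <- scaled[[1]]
  for (t in scaled[-1]) acc <- acc + t
  out <- structure(list(cov = acc / length(tracks), scale_factor = 1,
                        total_unique_reads = sum(vapply(tracks, function(t)
                          t$total_unique_reads, numeric(1))),
                        mean_tag_length = mean(vapply(tracks, function(t)
                          t$mean_tag_length, numeric(1))),
                        is_mean = TRUE),
                   class = "coverage_track")
  out
}

moving_average <- function(x, k) {
  if (k <= 1L || length(x) < 2L) return(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call peaks against a Poisson background
#'
#' A deliberately simple, fully specified caller: coverage is binned
#' (`bin_size` bp), bin mass is converted to an estimated tag count per
#' bin (bin coverage mass divided by the mean tag length), smoothed with a
#' centred moving average of `smooth_bins` bins, and thresholded at the
#' `1 - pval` quantile of a Poisson with the genome-wide mean bin count as
#' rate. Runs of super-threshold bins closer than `merge_gap` bp are
#' joined and runs shorter than `min_width` bp are dropped; each peak is
#' scored by its maximum smoothed bin count.
#'
#' @param track A [make_coverage()] track.
#' @param bin_size Bin width in bp.
#' @param smooth_bins Moving-average width in bins.
#' @param pval Poisson upper-tail probability for the bin threshold.
#' @param merge_gap Maximum gap (bp) between runs that are joined.
#' @param min_width Minimum peak width (bp).
#' @return A sorted, disjoint peak `GRanges` with `name` and `score`.
#' @export
call_peaks <- function(track, bin_size = 100L, smooth_bins = 3L,
                       pval = 1e-6, merge_gap = 200L, min_width = 200L) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$total_unique_reads == 0L) return(GenomicRanges::GRanges())
  binned <- lapply(names(track$cov), function(chrom) {
    r <- track$cov[[chrom]]
    len <- length(r)
    nb <- ceiling(len / bin_size)
    starts <- (seq_len(nb) - 1L) * bin_size + 1L
    ends <- pmin(starts + bin_size - 1L, len)
    v <- IRanges::viewSums(IRanges::Views(r, starts, ends))
    as.numeric(v) / track$mean_tag_length
  })
  names(binned) <- names(track$cov)
  lambda <- mean(unlist(binned))
  if (!is.finite(lambda) || lambda <= 0) return(GenomicRanges::GRanges())
  threshold <- stats::qpois(1 - pval, lambda)
  peaks <- list()
  for (chrom in names(binned)) {
    est <- moving_average(binned[[chrom]], smooth_bins)
    keep <- est > threshold
    if (!any(keep)) next
    runs <- rle(keep)
    ends_bin <- cumsum(runs$lengths)
    starts_bin <- ends_bin - runs$lengths + 1L
    on <- which(runs$values)
    iv <- IRanges::IRanges((starts_bin[on] - 1L) * bin_size + 1L,
                           pmin(ends_bin[on] * bin_size,
                                length(track$cov[[chrom]])))
    iv <- IRanges::reduce(iv, min.gapwidth = merge_gap)
    iv <- iv[IRanges::width(iv) >= min_width]
    if (!length(iv)) next
    sc <- vapply(seq_along(iv), function(i) {
      b1 <- (IRanges::start(iv)[i] - 1L) %/% bin_size + 1L
      b2 <- (IRanges::end(iv)[i] - 1L) %/% bin_size + 1L
      max(est[b1:b2])
    }, numeric(1))
    peaks[[chrom]] <- data.frame(chrom = chrom, start = IRanges::start(iv),
                                 end = IRanges::end(iv), score = sc)
  }
  if (!length(peaks)) return(GenomicRanges::GRanges())
  d <- do.call(rbind, unname(peaks))
  out <- GenomicRanges::sort(
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                           score = d$score),
    ignore.strand = TRUE)
  out$name <- sprintf("peak_%04d", seq_along(out))
  out
}
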