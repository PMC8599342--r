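BASES <- c("A", "C", "G", "T")

base_codes <- function(seq) {
  lookup <- rep(NA_integer_, 256L)
  lookup[utf8ToInt("A")] <- 1L; lookup[utf8ToInt("a")] <- 1L
  lookup[utf8ToInt("C")] <- 2L; lookup[utf8ToInt("c")] <- 2L
  lookup[utf8ToInt("G")] <- 3L; lookup[utf8ToInt("g")] <- 3L
  lookup[utf8ToInt("T")] <- 4L; lookup[utf8ToInt("t")] <- 4L
  lookup[utf8ToInt(as.character(seq))]
}

#' Build a position weight matrix from base counts
#'
#' Converts a 4 x width count (or probability) matrix into a PWM object
#' holding the pseudocount-normalized per-column base probabilities, the
#' log2-odds score matrix against the background model, the maximum
#' achievable score, and the match threshold (a fraction of that maximum).
#'
#' @param counts Numeric 4 x width matrix, rows in A, C, G, T order.
#' @param id Motif identifier.
#' @param pseudocount Added to every cell before normalization; must be > 0.
#' @param background Base frequencies (length 4, summing to 1).
#' @param threshold_frac Match threshold as a fraction of the maximum score.
#' @return An object of class `pwm`.
#' @export
#' @examples
#' m <- pwm_from_counts(matrix(c(97, 1, 1, 1), 4, 3), id = "toy")
#' m$consensus
pwm_from_counts <- function(counts, id, pseudocount = 1,
                            background = rep(0.25, 4),
                            threshold_frac = 0.6) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_usage("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L) stop_usage("motif width must be >= 4")
  if (pseudocount <= 0) stop_usage("pseudocount must be > 0")
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 4L) {
    stop_usage("background must be 4 frequencies summing to 1")
  }
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  rownames(prob) <- BASES
  log_odds <- log2(prob / background)
  max_score <- sum(apply(log_odds, 2, max))
  pwm <- list(id = id,
              consensus = paste(BASES[apply(prob, 2, which.max)], collapse = ""),
              prob = prob,
              width = ncol(prob),
              background = stats::setNames(background, BASES),
              pseudocount = pseudocount,
              log_odds = log_odds,
              max_score = max_score,
              threshold = threshold_frac * max_score)
  class(pwm) <- "pwm"
  pwm
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$id, ": width ", x$width, ", consensus ", x$consensus,
      ", threshold ", signif(x$threshold, 4), "/", signif(x$max_score, 4),
      "\n", sep = "")
  invisible(x)
}

#' Sample one sequence from a PWM
#'
#' Draws one base per column from the column's probability distribution,
#' so emitted instances vary around the consensus the way genomic binding
#' sites do.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @return A character string of length `pwm$width`.
#' @export
sample_pwm_instance <- function(pwm) {
  paste(vapply(seq_len(pwm$width),
               function(j) sample(BASES, 1L, prob = pwm$prob[, j]),
               character(1)), collapse = "")
}

#' Read motifs in JASPAR PFM format
#'
#' Parses the four-row `A [ ... ]` count block under each `>ID name`
#' header and builds one [pwm_from_counts()] object per record.
#'
#' @param path File path.
#' @inheritParams pwm_from_counts
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4),
                        threshold_frac = 0.6) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_usage("no motif records in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L) stop_usage("motif block must have 4 base rows: ", lines[heads[i]])
    id <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]][1]
    rows <- lapply(block, function(l) {
      s <- sub("^[ACGTacgt]", "", l)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    counts <- do.call(rbind, rows)
    out[[id]] <- pwm_from_counts(counts, id = id, pseudocount = pseudocount,
                                 background = background,
                                 threshold_frac = threshold_frac)
  }
  out
}

#' The shipped synthetic motif library
#'
#' Loads the package's built-in library of ten pluripotency-related motif
#' models (OCT4, SOX2, the OCT4-SOX2 composite, TEAD1-4, ZIC3, a KLF4-like
#' GC-box and a CTCF-like matrix). These matrices are synthetic
#' consensus-derived stand-ins constructed for this package — plausible
#' sharp PFMs with the canonical core of each family, not measured
#' genomic frequencies — which is all the screen's statistics require.
#'
#' @inheritParams pwm_from_counts
#' @return Named list of `pwm` objects.
#' @export
motif_library <- function(pseudocount = 1, background = rep(0.25, 4),
                          threshold_frac = 0.6) {
  path <- system.file("extdata", "motifs_synthetic.jaspar",
                      package = "atacscreen", mustWork = TRUE)
  read_jaspar(path, pseudocount = pseudocount, background = background,
              threshold_frac = threshold_frac)
}

score_windows <- function(codes, log_odds) {
  w <- ncol(log_odds)
  n <- length(codes)
  if (n < w) return(numeric(0))
  npos <- n - w + 1L
  s <- numeric(npos)
  idx <- seq_len(npos)
  for (j in seq_len(w)) {
    s <- s + log_odds[cbind(codes[idx + j - 1L], j)]
  }
  s[is.na(s)] <- -Inf   # windows containing a non-ACGT base never match
  s
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every window of `pwm$width` as the summed log2-odds of the
#' window's bases against the background model; the reverse strand is
#' scored on the reverse complement. All windows at or above the match
#' threshold are returned. Windows containing a non-ACGT base score
#' `-Inf` and are skipped.
#'
#' @param sequence A character string or `DNAString`.
#' @param pwm A [pwm_from_counts()] object.
#' @param threshold Log2-odds match threshold; defaults to the PWM's own.
#' @return A data.frame with one row per match: `offset` (1-based start of
#'   the matched window on the forward sequence), `strand`, `score`.
#' @export
#' @examples
#' m <- pwm_from_counts(matrix(c(97, 1, 1, 1), 4, 4), id = "polyA")
#' scan_pwm("GGAAAAGG", m)
scan_pwm <- function(sequence, pwm, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm$threshold
  codes <- base_codes(sequence)
  n <- length(codes)
  w <- pwm$width
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < w) return(empty)
  fwd <- score_windows(codes, pwm$log_odds)
  rc <- rev(5L - codes)                    # reverse complement codes
  rev_sc <- score_windows(rc, pwm$log_odds)
  hit_f <- which(fwd >= threshold)
  hit_r <- which(rev_sc >= threshold)
  out <- data.frame(
    offset = c(hit_f, n - hit_r - w + 2L),  # map rc offsets to forward coords
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev_sc[hit_r])
  )
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

has_pwm_match <- function(sequences, pwm, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm$threshold
  vapply(as.character(sequences), function(s) {
    codes <- base_codes(s)
    if (length(codes) < pwm$width) return(FALSE)
    if (any(score_windows(codes, pwm$log_odds) >= threshold)) return(TRUE)
    any(score_windows(rev(5L - codes), pwm$log_odds) >= threshold)
  }, logical(1), USE.NAMES = FALSE)
}

#' Extract fixed-width summit-centred peak sequences
#'
#' Trims/pads each peak to `width` bp around its midpoint (clamped to the
#' chromosome ends) and extracts the sequence, so per-peak motif
#' presence/absence is not biased by peak length.
#'
#' @param genome Named `DNAStringSet`.
#' @param peaks A `GRanges`.
#' @param width Extracted width in bp.
#' @return Character vector of sequences, one per peak.
#' @export
peak_sequences <- function(genome, peaks, width = 200L) {
  if (!length(peaks)) return(character(0))
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(chroms %in% names(genome))) {
    stop_usage("peaks reference chromosomes absent from the genome")
  }
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) %/% 2L
  half <- width %/% 2L
  out <- character(length(peaks))
  for (chrom in unique(chroms)) {
    i <- which(chroms == chrom)
    len <- length(genome[[chrom]])
    from <- pmax(1L, pmin(mid[i] - half + 1L, len - width + 1L))
    to <- pmin(len, from + width - 1L)
    out[i] <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(from, to)))
  }
  out
}

#' Hypergeometric motif enrichment of one peak group against another
#'
#' Counts peaks containing at least one PWM match in the target group
#' (`k` of `n`) and the background group (`K` of `N`) and tests
#' over-representation with the upper-tail cumulative hypergeometric:
#' the probability of drawing at least `k` motif-positive peaks in `n`
#' draws, without replacement, from the pooled `n + N` peaks of which
#' `k + K` are positive. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param target_seqs,background_seqs Character vectors of peak sequences
#'   (see [peak_sequences()]); both must be non-empty.
#' @param pwm A [pwm_from_counts()] object.
#' @param threshold Optional log2-odds threshold override.
#' @return One-row data.frame: `motif`, `k`, `n`, `K`, `N`, `fold`, `p`.
#' @export
enrichment_test <- function(target_seqs, background_seqs, pwm,
                            threshold = NULL) {
  if (!length(target_seqs) || !length(background_seqs)) {
    stop_usage("both peak groups must be non-empty")
  }
  k <- sum(has_pwm_match(target_seqs, pwm, threshold))
  K <- sum(has_pwm_match(background_seqs, pwm, threshold))
  n <- length(target_seqs)
  N <- length(background_seqs)
  p <- stats::phyper(k - 1, k + K, n + N - k - K, n, lower.tail = FALSE)
  fold <- if (K == 0) {
    if (k == 0) 1 else Inf
  } else {
    (k / n) / (K / N)
  }
  data.frame(motif = pwm$id, k = k, n = n, K = K, N = N, fold = fold, p = p)
}

#' Run the enrichment test over a motif library and rank the results
#'
#' @param target_seqs,background_seqs As in [enrichment_test()].
#' @param motifs Named list of `pwm` objects.
#' @return A ranked enrichment table (see [rank_motifs()]).
#' @export
enrichment_table <- function(target_seqs, background_seqs, motifs) {
  res <- do.call(rbind, lapply(motifs, function(m) {
    enrichment_test(target_seqs, background_seqs, m)
  }))
  rownames(res) <- NULL
  rank_motifs(res)
}

#' Benjamini-Hochberg adjust and order an enrichment table
#'
#' Adds a BH-adjusted p-value per motif and sorts ascending by adjusted
#' then raw p, breaking remaining ties by descending fold and motif id.
#' The result is invariant to the input row order.
#'
#' @param results A data.frame of [enrichment_test()] rows.
#' @return The same table with a `p_adj` column, ranked.
#' @export
rank_motifs <- function(results) {
  if (!nrow(results)) {
    results$p_adj <- numeric(0)
    return(results)
  }
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  ord <- order(results$p_adj, results$p, -results$fold, results$motif)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample a background peak group to match the target's GC profile
#'
#' Optional background construction mode: bins target sequences by GC
#' fraction and draws background sequences to reproduce the target's bin
#' proportions (without replacement, scaled down if a bin runs short).
#'
#' @param target_seqs,background_seqs Character vectors of sequences.
#' @param bins Number of GC bins.
#' @return Integer indices into `background_seqs`.
#' @export
gc_match_background <- function(target_seqs, background_seqs, bins = 5L) {
  gc_of <- function(s) {
    codes <- base_codes(s)
    mean(codes == 2L | codes == 3L, na.rm = TRUE)
  }
  gt <- vapply(target_seqs, gc_of, numeric(1), USE.NAMES = FALSE)
  gb <- vapply(background_seqs, gc_of, numeric(1), USE.NAMES = FALSE)
  breaks <- unique(stats::quantile(c(gt, gb), probs = seq(0, 1, length.out = bins + 1L)))
  bt <- cut(gt, breaks, include.lowest = TRUE)
  bb <- cut(gb, breaks, include.lowest = TRUE)
  prop <- table(bt) / length(bt)
  avail <- table(bb)
  # largest total background size whose per-bin demand is available
  total <- min(floor(avail[prop > 0] / prop[prop > 0]), length(background_seqs))
  want <- round(prop * total)
  idx <- unlist(lapply(names(want), function(b) {
    pool <- which(as.character(bb) == b)
    if (!length(pool) || want[[b]] == 0) return(integer(0))
    sample(pool, min(want[[b]], length(pool)))
  }))
  sort(idx)
}
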