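# Shared fixtures and independent oracles. Oracles deliberately use naive
# code paths (per-offset loops, combinatorial counting, closed forms) that
# share nothing with the package implementation they check.

rand_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_tags <- function(chrom, start, width = 50L, strand = "+", mapq = 60L,
                      seqlengths = NULL) {
  n <- length(start)
  GenomicRanges::GRanges(rep(chrom, length.out = n),
                         IRanges::IRanges(start, width = width),
                         strand = rep(strand, length.out = n),
                         mapq = rep(as.integer(mapq), length.out = n),
                         seqlengths = seqlengths)
}

# sharp PWM with probability p on the consensus base (tiny pseudocount so
# column probabilities stay at the requested values to ~1e-9)
sharp_pwm <- function(consensus, p = 0.97, id = "test", threshold_frac = 0.6) {
  cc <- strsplit(consensus, "")[[1]]
  counts <- matrix((1 - p) / 3, 4, length(cc),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cc)) counts[cc[j], j] <- p
  pwm_from_counts(counts, id = id, pseudocount = 1e-9,
                  threshold_frac = threshold_frac)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive per-offset PWM scan: rescopes every window from the probability
# matrix, both strands, without the vectorized window machinery
oracle_scan <- function(sequence, pwm, threshold = pwm$threshold) {
  hits <- list()
  score_at <- function(s, i) {
    total <- 0
    for (j in seq_len(pwm$width)) {
      b <- substr(s, i + j - 1L, i + j - 1L)
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      total <- total + log2(pwm$prob[b, j] / pwm$background[b])
    }
    total
  }
  n <- nchar(sequence)
  rc <- revcomp_chr(sequence)
  for (i in seq_len(max(n - pwm$width + 1L, 0L))) {
    sf <- score_at(sequence, i)
    if (sf >= threshold) {
      hits[[length(hits) + 1L]] <- data.frame(offset = i, strand = "+", score = sf)
    }
    sr <- score_at(rc, i)
    if (sr >= threshold) {
      hits[[length(hits) + 1L]] <- data.frame(offset = n - i - pwm$width + 2L,
                                              strand = "-", score = sr)
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact upper-tail hypergeometric by combinatorial counting of draws
oracle_hyper <- function(k, n, K, N) {
  m <- k + K
  tot <- n + N
  js <- k:min(n, m)
  sum(choose(m, js) * choose(tot - m, n - js)) / choose(tot, n)
}

# textbook pooled-variance two-sample t
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# peak group with exactly n_pos sequences containing a guaranteed PWM match
# (the consensus) and the rest containing none (low-scoring homopolymer)
presence_seqs <- function(n_pos, n_total, consensus = "ATAATTAA") {
  c(rep(consensus, n_pos), rep(strrep("C", nchar(consensus)), n_total - n_pos))
}

# disjoint random peaks: one optional peak per fixed-width slot
random_disjoint_peaks <- function(n, chrom = "chr1", genome_len = 1e6,
                                  slot = 1000L, min_w = 50L, max_w = 800L) {
  slots <- sample.int(genome_len %/% slot, n)
  w <- sample(min_w:max_w, n, replace = TRUE)
  start <- (slots - 1L) * slot + sample.int(slot - max_w, n, replace = TRUE)
  GenomicRanges::sort(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, width = w)))
}
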