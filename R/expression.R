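#' GC-normalize a count matrix
#'
#' Within each sample, genes are binned by GC fraction (quantile bins) and
#' every gene's count is rescaled by `global / bin_median`, where `global`
#' is the median of the bin medians of that sample. An optional second
#' step rescales each sample so its upper quartile (over nonzero values)
#' matches the across-sample mean upper quartile. Zero counts stay zero
#' (both steps are multiplicative), and the whole procedure is idempotent.
#' Bins whose median is zero are skipped with a warning.
#'
#' Output values are "GC-normalized counts": comparable across GC strata
#' within a sample and, with the upper-quartile step, across samples.
#'
#' @param em An `expr_matrix`.
#' @param n_bins Number of GC bins.
#' @param upper_quartile Apply the between-sample upper-quartile step?
#' @return The normalized `expr_matrix` (`normalized = TRUE`).
#' @export
gc_normalize <- function(em, n_bins = 10L, upper_quartile = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  gc <- em$genes$gc_fraction
  breaks <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_bins + 1L)))
  bins <- cut(gc, breaks, include.lowest = TRUE)
  if (any(table(bins) < 2L)) {
    stop_usage("each occupied GC bin needs at least 2 genes")
  }
  counts <- em$counts
  for (j in seq_len(ncol(counts))) {
    med <- tapply(counts[, j], bins, stats::median)
    usable <- !is.na(med) & med > 0
    if (any(!usable)) {
      warning("sample ", colnames(counts)[j], ": ", sum(!usable),
              " degenerate GC bin(s) skipped")
    }
    if (!any(usable)) next
    global <- stats::median(med[usable])
    factor <- rep(1, nlevels(bins))
    factor[usable] <- global / med[usable]
    counts[, j] <- counts[, j] * factor[as.integer(bins)]
  }
  if (upper_quartile) {
    uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75))
    target <- mean(uq)
    counts <- sweep(counts, 2, target / uq, "*")
  }
  new_expr_matrix(counts, em$genes, em$samples, normalized = TRUE)
}

samples_of_state <- function(em, state) {
  s <- em$samples$sample[em$samples$state == state]
  if (!length(s)) stop_usage("unknown state: ", state)
  s
}

#' Per-gene replicate mean and SEM for one state
#'
#' Arithmetic mean across the state's replicates and standard error of the
#' mean (`sd / sqrt(n)`). With a single replicate the SEM is reported as 0
#' and the result carries `sem_defined = FALSE`.
#'
#' @param em An `expr_matrix`.
#' @param state State label.
#' @return data.frame `gene`, `mean`, `sem`, `n`, with attribute
#'   `sem_defined`.
#' @export
replicate_mean <- function(em, state) {
  stopifnot(inherits(em, "expr_matrix"))
  cols <- samples_of_state(em, state)
  x <- em$counts[, cols, drop = FALSE]
  n <- length(cols)
  m <- rowMeans(x)
  sem <- if (n >= 2L) apply(x, 1, stats::sd) / sqrt(n) else rep(0, nrow(x))
  out <- data.frame(gene = em$genes$gene, mean = m, sem = sem, n = n,
                    row.names = NULL)
  attr(out, "sem_defined") <- n >= 2L
  out
}

#' Classify state-specific highly expressed genes
#'
#' A gene is `A_high` iff its replicate-mean abundance in state A is at
#' least `min_expr` and exceeds state B's mean (plus the pseudo-abundance
#' `eps`) by at least `min_fc`-fold; symmetrically for `B_high`; all
#' remaining genes are `null`. The matrix should already be GC-normalized.
#'
#' @param em A normalized `expr_matrix`.
#' @param state_a,state_b State labels (A is the screen's target state).
#' @param min_fc Minimum fold change (must be >= 1).
#' @param min_expr Minimum mean normalized count in the high state.
#' @param eps Pseudo-abundance added to the comparison denominator.
#' @return data.frame of differential calls: `gene`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `log2fc` (A vs B, with `eps` on both sides),
#'   `class`.
#' @export
classify_highly_expressed <- function(em, state_a, state_b, min_fc = 2,
                                      min_expr = 30, eps = 1) {
  if (min_fc < 1) stop_usage("min_fc must be >= 1")
  if (!isTRUE(em$normalized)) {
    warning("expression matrix is not flagged GC-normalized")
  }
  ma <- replicate_mean(em, state_a)
  mb <- replicate_mean(em, state_b)
  a_high <- ma$mean >= min_expr & ma$mean / (mb$mean + eps) >= min_fc
  b_high <- mb$mean >= min_expr & mb$mean / (ma$mean + eps) >= min_fc
  cls <- ifelse(a_high, "A_high", ifelse(b_high, "B_high", "null"))
  data.frame(gene = ma$gene, mean_a = ma$mean, mean_b = mb$mean,
             sem_a = ma$sem, sem_b = mb$sem,
             log2fc = log2((ma$mean + eps) / (mb$mean + eps)),
             class = cls, row.names = NULL)
}

#' Two-sample pooled-variance t test for one gene
#'
#' The classic unpaired two-tailed Student t test (equal-variance pooled
#' form) comparing a gene's replicates between two states. With n = 2 per
#' state, as in a two-donor design, the test has little power; the
#' p-value is reported with a `low_power` flag when either group has
#' fewer than 3 replicates. Degenerate inputs: all values equal gives
#' t = 0, p = 1; zero variance in both groups with unequal means gives
#' p = 0 with a warning.
#'
#' @param em An `expr_matrix`.
#' @param gene Gene id.
#' @param state_a,state_b State labels.
#' @param alpha Significance level used to assign the class.
#' @return One-row data.frame: `gene`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `t`, `df`, `p`, `class`, `low_power`.
#' @export
tf_expression_test <- function(em, gene, state_a, state_b, alpha = 0.05) {
  stopifnot(inherits(em, "expr_matrix"))
  i <- match(gene, em$genes$gene)
  if (is.na(i)) stop_usage("gene not in matrix: ", gene)
  x <- em$counts[i, samples_of_state(em, state_a)]
  y <- em$counts[i, samples_of_state(em, state_b)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_usage("tf_expression_test needs >= 2 replicates per state")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      tt <- list(statistic = 0, parameter = length(x) + length(y) - 2L,
                 p.value = 1)
    } else {
      warning("zero variance in both groups with unequal means: p -> 0")
      tt <- list(statistic = sign(mean(x) - mean(y)) * Inf,
                 parameter = length(x) + length(y) - 2L, p.value = 0)
    }
  } else {
    fit <- stats::t.test(x, y, var.equal = TRUE)
    tt <- list(statistic = unname(fit$statistic),
               parameter = unname(fit$parameter), p.value = fit$p.value)
  }
  cls <- if (tt$p.value <= alpha) {
    if (mean(x) > mean(y)) "A_high" else "B_high"
  } else "null"
  data.frame(gene = gene, mean_a = mean(x), mean_b = mean(y),
             sem_a = stats::sd(x) / sqrt(length(x)),
             sem_b = stats::sd(y) / sqrt(length(y)),
             t = tt$statistic, df = tt$parameter, p = tt$p.value,
             class = cls,
             low_power = length(x) < 3L || length(y) < 3L,
             row.names = NULL)
}
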