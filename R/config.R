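#' Simulation configuration for the synthetic two-state landscape
#'
#' Collects every tunable of the synthetic-data generator: genome geometry,
#' planted region layout, motif planting probabilities, ATAC tag library
#' composition (depth, duplicate / mitochondrial / low-MAPQ contamination),
#' and the negative-binomial expression model with its GC bias.
#'
#' Defaults describe a miniature version of a two-cell-state comparison
#' (a pluripotent-like state "A" versus a somatic-like state "B"): two
#' 100 kb nuclear chromosomes plus a 16 kb mitochondrial chromosome, 30
#' accessible regions per class, two ATAC replicates per state as in a
#' two-donor design, and a 2,000-gene count matrix with planted
#' state-specific genes.
#'
#' @param chrom_lengths Named integer vector of nuclear chromosome lengths.
#' @param chrm_length Length of the mitochondrial chromosome (named "chrM").
#' @param gc_content Target genome GC fraction.
#' @param n_regions Named vector: regions per class
#'   (`A_specific`, `B_specific`, `shared`).
#' @param region_width Width (bp) of each planted accessible region.
#' @param target_motifs Motif ids planted at `plant_prob_target` in
#'   A-specific regions and whose TF genes are truly A-high.
#' @param decoy_motifs Motif ids planted like targets but whose TF genes
#'   stay at null expression (the enriched-motif / flat-expression pattern).
#' @param plant_prob_target,plant_prob_background Per-region Bernoulli
#'   planting probabilities for target/decoy motifs in A-specific regions
#'   versus every other motif-region combination.
#' @param tags_per_replicate ATAC tags per replicate library.
#' @param n_replicates ATAC replicates per state.
#' @param tag_length Tag length in bp.
#' @param enrichment Per-base tag density ratio, open regions over background.
#' @param dup_rate,chrm_rate,low_mapq_rate Fractions of tags that are exact
#'   duplicates, mitochondrial, or below the MAPQ threshold.
#' @param n_genes Genes in the count matrix (TF genes are added on top).
#' @param n_de_genes Named vector: planted `A_high` and `B_high` gene counts.
#' @param de_lfc Absolute log2 fold change of planted differential genes.
#' @param tf_lfc Log2 fold change given to target-TF genes.
#' @param base_mean_log_mean,base_mean_log_sd Lognormal parameters of the
#'   per-gene baseline mean.
#' @param dispersion Negative-binomial size parameter (larger = less noise).
#' @param gc_bias_slope Planted GC bias, in log2 fold change per unit GC.
#' @param n_expr_replicates RNA-seq replicates per state.
#' @param states Length-2 character vector of state labels; the first is the
#'   "target" state of the screen.
#' @param seed Master seed; every stochastic stage derives its stream from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$tags_per_replicate
sim_config <- function(chrom_lengths = c(chr1 = 150000L, chr2 = 150000L),
                       chrm_length = 16000L,
                       gc_content = 0.41,
                       n_regions = c(A_specific = 50L, B_specific = 50L, shared = 50L),
                       region_width = 500L,
                       target_motifs = c("TEAD2", "TEAD4", "ZIC3"),
                       decoy_motifs = "TEAD1",
                       plant_prob_target = 0.8,
                       plant_prob_background = 0.05,
                       tags_per_replicate = 20000L,
                       n_replicates = 2L,
                       tag_length = 50L,
                       enrichment = 10,
                       dup_rate = 0.2,
                       chrm_rate = 0.3,
                       low_mapq_rate = 0.15,
                       n_genes = 2000L,
                       n_de_genes = c(A_high = 200L, B_high = 150L),
                       de_lfc = 3,
                       tf_lfc = 3,
                       base_mean_log_mean = log(100),
                       base_mean_log_sd = 1,
                       dispersion = 20,
                       gc_bias_slope = 3,
                       n_expr_replicates = 2L,
                       states = c("A", "B"),
                       seed = 1L) {
  cfg <- list(
    chrom_lengths = chrom_lengths, chrm_length = chrm_length,
    gc_content = gc_content, n_regions = n_regions,
    region_width = region_width, target_motifs = target_motifs,
    decoy_motifs = decoy_motifs, plant_prob_target = plant_prob_target,
    plant_prob_background = plant_prob_background,
    tags_per_replicate = tags_per_replicate, n_replicates = n_replicates,
    tag_length = tag_length, enrichment = enrichment, dup_rate = dup_rate,
    chrm_rate = chrm_rate, low_mapq_rate = low_mapq_rate,
    n_genes = n_genes, n_de_genes = n_de_genes, de_lfc = de_lfc,
    tf_lfc = tf_lfc, base_mean_log_mean = base_mean_log_mean,
    base_mean_log_sd = base_mean_log_sd, dispersion = dispersion,
    gc_bias_slope = gc_bias_slope, n_expr_replicates = n_expr_replicates,
    states = states, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$chrom_lengths) < 1L || any(cfg$chrom_lengths <= 0) ||
      is.null(names(cfg$chrom_lengths)) || anyDuplicated(names(cfg$chrom_lengths))) {
    stop_usage("chrom_lengths must be a named vector of positive unique-named lengths")
  }
  if ("chrM" %in% names(cfg$chrom_lengths)) {
    stop_usage("'chrM' is reserved for the mitochondrial chromosome; set chrm_length")
  }
  if (!is_count(cfg$chrm_length)) stop_usage("chrm_length must be a positive integer")
  if (!is_rate(cfg$gc_content)) stop_usage("gc_content must lie in [0, 1]")
  need <- c("A_specific", "B_specific", "shared")
  if (!all(need %in% names(cfg$n_regions)) || any(cfg$n_regions < 0)) {
    stop_usage("n_regions must name A_specific, B_specific and shared counts")
  }
  for (f in c("plant_prob_target", "plant_prob_background", "dup_rate",
              "chrm_rate", "low_mapq_rate")) {
    if (!is_rate(cfg[[f]])) stop_usage(f, " must lie in [0, 1]")
  }
  for (f in c("region_width", "n_replicates",
              "tag_length", "n_genes", "n_expr_replicates")) {
    if (!is_count(cfg[[f]])) stop_usage(f, " must be a positive integer")
  }
  if (!is_count(cfg$tags_per_replicate) && cfg$tags_per_replicate != 0) {
    stop_usage("tags_per_replicate must be a non-negative integer")
  }
  if (cfg$dispersion <= 0) stop_usage("dispersion must be positive")
  if (cfg$enrichment < 1) stop_usage("enrichment must be >= 1")
  if (length(cfg$states) != 2L || anyDuplicated(cfg$states)) {
    stop_usage("states must be two distinct labels")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) stop_usage("seed must be a single integer")
  invisible(cfg)
}

#' Analysis configuration for the full screen
#'
#' Bundles a [sim_config()] with every downstream threshold: the MAPQ
#' cutoff, mitochondrial chromosome names, peak-caller settings, the peak
#' overlap rule, the TSS window, PWM score policy, GC-normalization bins,
#' expression classification thresholds and the nomination alpha.
#'
#' @param sim A [sim_config()].
#' @param min_mapq Minimum mapping quality retained (tags with
#'   `mapq >= min_mapq` are kept, matching `samtools view -q`).
#' @param mito_names Chromosome names treated as mitochondrial.
#' @param bin_size,smooth_bins,peak_pval,merge_gap,min_width Peak-caller
#'   settings: bin width (bp), moving-average width (bins), Poisson
#'   upper-tail probability for the bin threshold, maximum gap (bp) between
#'   runs that are joined, and minimum peak width (bp).
#' @param min_overlap Minimum overlap (bp) for two peaks to be "shared".
#' @param tss_window Maximum TSS-to-peak distance (bp) for gene linkage.
#' @param pwm_threshold_frac PWM match threshold as a fraction of each
#'   motif's maximum achievable log-odds score.
#' @param peak_seq_width Width (bp) of the summit-centred sequence scanned
#'   per peak.
#' @param gc_bins GC bins used by [gc_normalize()].
#' @param min_fc,min_expr,expr_eps Highly-expressed-gene classification:
#'   minimum fold change, minimum mean normalized count in the high state,
#'   and the pseudo-abundance added to the denominator.
#' @param alpha Adjusted-p cutoff for calling a motif enriched.
#' @param score_formula `"product"` (`-log10(p_adj) * max(log2FC, 0)`) or
#'   `"pvalue_only"`.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(sim = sim_config(),
                          min_mapq = 35L,
                          mito_names = "chrM",
                          bin_size = 100L,
                          smooth_bins = 3L,
                          peak_pval = 1e-6,
                          merge_gap = 200L,
                          min_width = 200L,
                          min_overlap = 1L,
                          tss_window = 10000L,
                          pwm_threshold_frac = 0.6,
                          peak_seq_width = 200L,
                          gc_bins = 10L,
                          min_fc = 2,
                          min_expr = 30,
                          expr_eps = 1,
                          alpha = 0.05,
                          score_formula = c("product", "pvalue_only")) {
  score_formula <- match.arg(score_formula)
  cfg <- list(sim = sim, min_mapq = min_mapq, mito_names = mito_names,
              bin_size = bin_size, smooth_bins = smooth_bins,
              peak_pval = peak_pval, merge_gap = merge_gap,
              min_width = min_width, min_overlap = min_overlap,
              tss_window = tss_window, pwm_threshold_frac = pwm_threshold_frac,
              peak_seq_width = peak_seq_width, gc_bins = gc_bins,
              min_fc = min_fc, min_expr = min_expr, expr_eps = expr_eps,
              alpha = alpha, score_formula = score_formula)
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  validate_sim_config(cfg$sim)
  if (cfg$min_mapq < 0) stop_usage("min_mapq must be >= 0")
  for (f in c("bin_size", "smooth_bins", "merge_gap", "min_width",
              "min_overlap", "tss_window", "peak_seq_width", "gc_bins")) {
    if (!is_count(cfg[[f]]) && cfg[[f]] != 0) stop_usage(f, " must be a non-negative integer")
  }
  if (!is_rate(cfg$peak_pval) || cfg$peak_pval <= 0) stop_usage("peak_pval must lie in (0, 1]")
  if (!is_rate(cfg$pwm_threshold_frac)) stop_usage("pwm_threshold_frac must lie in [0, 1]")
  if (cfg$min_fc < 1) stop_usage("min_fc must be >= 1")
  if (!is_rate(cfg$alpha)) stop_usage("alpha must lie in [0, 1]")
  invisible(cfg)
}

#' Read / write a screen configuration as YAML
#'
#' The whole configuration serializes to a single YAML document. Unknown
#' keys are rejected so that typos fail loudly instead of silently falling
#' back to defaults.
#'
#' @param path File path.
#' @param cfg A [screen_config()].
#' @return `read_screen_config()` returns a `screen_config`;
#'   `write_screen_config()` returns `path` invisibly.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_raw <- raw$sim
  raw$sim <- NULL
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) stop_usage("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(raw, setdiff(names(formals(screen_config)), "sim"), "screen_config")
  check_keys(sim_raw, names(formals(sim_config)), "sim_config")
  # yaml reads named vectors back as lists; restore atomic shape
  fix <- function(x) if (is.list(x)) unlist(x) else x
  sim_raw <- lapply(sim_raw, fix)
  sim <- do.call(sim_config, sim_raw)
  do.call(screen_config, c(list(sim = sim), raw))
}

#' @rdname read_screen_config
#' @export
write_screen_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screen_config"))
  out <- unclass(cfg)
  # named vectors serialize as YAML maps so their names survive the trip
  out$sim <- lapply(as.list(unclass(cfg$sim)), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", length(x$chrom_lengths), " nuclear chrom(s) + chrM (",
      x$chrm_length, " bp), ", sum(x$n_regions), " regions, ",
      x$tags_per_replicate, " tags/replicate, ", x$n_genes, " genes, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("screen_config (alpha ", x$alpha, ", min_fc ", x$min_fc,
      ", tss_window ", x$tss_window, " bp)\n", sep = "")
  print(x$sim)
  invisible(x)
}
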