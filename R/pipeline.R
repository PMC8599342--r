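#' Run the full screen on synthetic data
#'
#' Executes every stage end to end: simulate the two-state landscape,
#' filter each ATAC replicate (MAPQ, mitochondrial, duplicates), merge
#' replicates per state, build scaled coverage, call peaks, classify
#' state-specific and shared peaks, link target-state peaks to genes by
#' TSS proximity, test motif enrichment of the target-state-specific
#' group against the opposite group, GC-normalize the counts and classify
#' highly expressed genes, then nominate and rank candidate TFs.
#'
#' With a fixed configuration (whose seed drives every stochastic step)
#' the run is deterministic: two invocations produce byte-identical
#' output files.
#'
#' @param config A [screen_config()].
#' @param outdir Optional output directory; when given, every stage's
#'   tables are written there (tagAlign, bedGraph, BED, TSV, plus
#'   `candidates.tsv` and `report.json`).
#' @param motifs Motif library; defaults to the shipped one scanned at
#'   `config$pwm_threshold_frac`.
#' @return A list of class `screen_result`: the simulated inputs, every
#'   intermediate, the candidate table and the report.
#' @export
#' @examples
#' \donttest{
#' res <- run_screen(screen_config(sim = sim_config(seed = 7)))
#' res$candidates
#' }
run_screen <- function(config = screen_config(), outdir = NULL,
                       motifs = NULL) {
  validate_screen_config(config)
  if (is.null(motifs)) {
    motifs <- motif_library(threshold_frac = config$pwm_threshold_frac)
  }
  sim <- simulate_landscape(config$sim, motifs)
  states <- config$sim$states

  filtered <- lapply(sim$tags, function(reps) {
    lapply(reps, filter_tags, min_mapq = config$min_mapq,
           mito_names = config$mito_names)
  })
  merged <- lapply(filtered, merge_replicates)
  tracks <- lapply(merged, make_coverage)
  peaks <- lapply(tracks, call_peaks, bin_size = config$bin_size,
                  smooth_bins = config$smooth_bins, pval = config$peak_pval,
                  merge_gap = config$merge_gap, min_width = config$min_width)

  cls <- classify_peaks(peaks[[states[1]]], peaks[[states[2]]],
                        min_overlap = config$min_overlap)
  links <- assign_peaks_to_genes(cls$A_specific, sim$truth$tss,
                                 window = config$tss_window)

  if (!length(cls$A_specific) || !length(cls$B_specific)) {
    stop("no state-specific peaks on one side; cannot run the enrichment contrast")
  }
  target_seqs <- peak_sequences(sim$genome, cls$A_specific,
                                width = config$peak_seq_width)
  background_seqs <- peak_sequences(sim$genome, cls$B_specific,
                                    width = config$peak_seq_width)
  enrich <- enrichment_table(target_seqs, background_seqs, motifs)

  norm <- gc_normalize(sim$expr, n_bins = config$gc_bins)
  de <- classify_highly_expressed(norm, states[1], states[2],
                                  min_fc = config$min_fc,
                                  min_expr = config$min_expr,
                                  eps = config$expr_eps)
  tf_tests <- do.call(rbind, lapply(sim$truth$tf_gene_links$tf_gene,
    function(g) tf_expression_test(norm, g, states[1], states[2],
                                   alpha = config$alpha)))

  candidates <- nominate(enrich, de, sim$truth$tf_gene_links,
                         alpha = config$alpha,
                         score_formula = config$score_formula)

  stage_counts <- list(
    tags_raw = lapply(sim$tags, function(reps) lapply(reps, length)),
    tags_filtered = lapply(filtered, function(reps) lapply(reps, length)),
    tags_merged = lapply(merged, length),
    peaks = lapply(peaks, length),
    peaks_a_specific = length(cls$A_specific),
    peaks_b_specific = length(cls$B_specific),
    peaks_shared_pairs = nrow(cls$pairs),
    gene_peak_links = nrow(links),
    genes_a_high = sum(de$class == "A_high"),
    genes_b_high = sum(de$class == "B_high"),
    motifs_tested = nrow(enrich),
    candidates = sum(candidates$verdict == "candidate")
  )
  report <- build_report(candidates, stage_counts, config, config$sim$seed)

  result <- structure(list(
    config = config, genome = sim$genome, truth = sim$truth,
    tags = sim$tags, filtered = filtered, merged = merged,
    tracks = tracks, peaks = peaks, classification = cls, links = links,
    enrichment = enrich, expr = sim$expr, expr_norm = norm, de = de,
    tf_tests = tf_tests, candidates = candidates, report = report
  ), class = "screen_result")

  if (!is.null(outdir)) write_screen_result(result, outdir)
  result
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write every stage of a screen result to disk
#'
#' @param result A [run_screen()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_screen_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_fasta(result$genome, fp("genome.fa"))
  write_truth_table(result$truth, fp("truth.json"))
  for (state in names(result$tags)) {
    for (rep in names(result$tags[[state]])) {
      write_tagalign(result$tags[[state]][[rep]],
                     fp(sprintf("tags_%s_%s.tagAlign", state, rep)))
      write_tagalign(result$filtered[[state]][[rep]],
                     fp(sprintf("filtered_%s_%s.tagAlign", state, rep)))
    }
    write_bedgraph(result$tracks[[state]], fp(sprintf("coverage_%s.bedGraph", state)))
    write_bed(result$peaks[[state]], fp(sprintf("peaks_%s.bed", state)))
  }
  write_bed(result$classification$A_specific, fp("peaks_A_specific.bed"))
  write_bed(result$classification$B_specific, fp("peaks_B_specific.bed"))
  write_bed(c(result$classification$shared_a, result$classification$shared_b),
            fp("peaks_shared.bed"))
  write_bed(result$truth$tss, fp("tss.bed"))
  data.table::fwrite(result$links, fp("gene_peak_links.tsv"), sep = "\t",
                     quote = FALSE, eol = "\n")
  write_expr_matrix(result$expr, fp("counts.tsv"), fp("samples.tsv"))
  write_expr_matrix(result$expr_norm, fp("counts_normalized.tsv"))
  data.table::fwrite(result$de, fp("differential_calls.tsv"), sep = "\t",
                     quote = FALSE, eol = "\n")
  data.table::fwrite(result$tf_tests, fp("tf_tests.tsv"), sep = "\t",
                     quote = FALSE, eol = "\n")
  data.table::fwrite(result$enrichment, fp("enrichment.tsv"), sep = "\t",
                     quote = FALSE, eol = "\n")
  data.table::fwrite(result$candidates, fp("candidates.tsv"), sep = "\t",
                     quote = FALSE, eol = "\n")
  write_report(result$report, fp("report.json"))
  invisible(outdir)
}
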