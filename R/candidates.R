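#' Nominate and rank candidate transcription factors
#'
#' Joins per-motif enrichment (target-state-specific peaks versus the
#' opposite group) with per-gene differential expression through the
#' TF-gene-to-motif map, and assigns each TF a verdict:
#' `candidate` (enriched motif AND A-high expression), `motif_only`
#' (enriched motif, expression not A-high — the pattern by which family
#' members with flat expression are excluded despite a shared enriched
#' motif), `expression_only`, or `rejected`. When several TFs map to one
#' motif each is evaluated independently on its own expression.
#'
#' The rank score is `-log10(p_adj) * max(log2FC, 0)` (`"product"`), a
#' total order monotone in both evidence axes, or `-log10(p_adj)`
#' (`"pvalue_only"`). TFs whose motif or gene is missing from the inputs
#' are flagged and excluded from the ranking with a warning.
#'
#' @param enrichments A ranked enrichment table ([enrichment_table()]).
#' @param de_calls Differential calls ([classify_highly_expressed()]).
#' @param tf_map data.frame with columns `tf_gene`, `motif`.
#' @param alpha Adjusted-p cutoff for motif enrichment.
#' @param score_formula `"product"` or `"pvalue_only"`.
#' @return data.frame sorted by descending score: `tf_gene`, `motif`,
#'   `p_adj`, `fold`, `log2fc`, `expr_class`, `score`, `verdict`.
#' @export
nominate <- function(enrichments, de_calls, tf_map, alpha = 0.05,
                     score_formula = c("product", "pvalue_only")) {
  score_formula <- match.arg(score_formula)
  if (!all(c("tf_gene", "motif") %in% names(tf_map))) {
    stop_usage("tf_map needs 'tf_gene' and 'motif' columns")
  }
  mi <- match(tf_map$motif, enrichments$motif)
  gi <- match(tf_map$tf_gene, de_calls$gene)
  missing <- is.na(mi) | is.na(gi)
  if (any(missing)) {
    warning("excluded from ranking (no motif enrichment or expression record): ",
            paste(tf_map$tf_gene[missing], collapse = ", "))
  }
  tf_map <- tf_map[!missing, , drop = FALSE]
  mi <- mi[!missing]; gi <- gi[!missing]
  p_adj <- enrichments$p_adj[mi]
  log2fc <- de_calls$log2fc[gi]
  expr_class <- de_calls$class[gi]
  enriched <- p_adj <= alpha
  a_high <- expr_class == "A_high"
  verdict <- ifelse(enriched & a_high, "candidate",
                    ifelse(enriched, "motif_only",
                           ifelse(a_high, "expression_only", "rejected")))
  neglogp <- -log10(pmax(p_adj, 1e-300))
  score <- switch(score_formula,
                  product = neglogp * pmax(log2fc, 0),
                  pvalue_only = neglogp)
  out <- data.frame(tf_gene = tf_map$tf_gene, motif = tf_map$motif,
                    p_adj = p_adj, fold = enrichments$fold[mi],
                    log2fc = log2fc, expr_class = expr_class,
                    score = score, verdict = verdict, row.names = NULL)
  out[order(-out$score, out$tf_gene), , drop = FALSE]
}

#' Build the structured run report
#'
#' Machine-readable summary of a screen: package version, seed, all
#' resolved thresholds, per-stage counts and the ranked candidate list.
#' Serializes to JSON with [write_report()]; the JSON round-trips through
#' [read_report()] byte-identically.
#'
#' @param candidates A [nominate()] table.
#' @param stage_counts Named list of per-stage counts.
#' @param config The [screen_config()] used.
#' @param seed The run seed.
#' @return A list of class `screen_report`.
#' @export
build_report <- function(candidates, stage_counts, config, seed) {
  if (nrow(candidates)) {
    # infinite fold (motif absent from the background) serializes as null
    candidates$fold[!is.finite(candidates$fold)] <- NA_real_
  }
  structure(list(
    tool = "atacscreen",
    version = as.character(utils::packageVersion("atacscreen")),
    seed = seed,
    parameters = report_parameters(config),
    stage_counts = stage_counts,
    n_candidates = sum(candidates$verdict == "candidate"),
    candidates = candidates
  ), class = "screen_report")
}

report_parameters <- function(config) {
  p <- unclass(config)
  p$sim <- lapply(unclass(p$sim), function(x) {
    if (!is.null(names(x)) && length(x) > 1L) as.list(x) else x
  })
  # the external caller settings the screen's design mirrors are recorded
  # as provenance metadata only; the built-in caller's own settings are
  # the bin_size/smooth_bins/peak_pval fields
  p$reference_caller <- "DFilter -bs=100 -ks=60 -refine (metadata only; not used)"
  p
}

#' @rdname build_report
#' @param report A `screen_report` (or the list read back from JSON).
#' @param path File path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname build_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("atacscreen report (seed ", x$seed, "): ", x$n_candidates,
      " candidate(s)\n", sep = "")
  if (nrow(x$candidates)) {
    print(x$candidates[, c("tf_gene", "motif", "p_adj", "log2fc", "score",
                           "verdict")], row.names = FALSE)
  }
  invisible(x)
}
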