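#' Read and write genome FASTA
#'
#' Thin wrappers around Biostrings that return/accept a named
#' `DNAStringSet`. Both single-line and wrapped FASTA dialects are read;
#' duplicate record names are rejected.
#'
#' @param path File path.
#' @param genome A named `DNAStringSet`.
#' @param width Line width used when writing.
#' @return `read_fasta()` returns a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each header, as aligners do
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop_usage("duplicate sequence names in ", path)
  x
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

tags_to_dt <- function(tags) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(tags)),
    start = GenomicRanges::start(tags) - 1L,   # 0-based half-open on disk
    end = GenomicRanges::end(tags),
    name = if (!is.null(tags$name)) tags$name else ".",
    score = if (!is.null(tags$mapq)) tags$mapq else 0L,
    strand = as.character(GenomicRanges::strand(tags))
  )
}

#' Read and write tagAlign files
#'
#' tagAlign is 6-column BED (chrom, start, end, name, score, strand) with
#' one sequenced tag per row; the score column carries the mapping quality.
#' Coordinates are 0-based half-open on disk and converted to 1-based
#' `GRanges` in memory.
#'
#' @param path File path.
#' @param tags A `GRanges` with a `mapq` metadata column.
#' @return `read_tagalign()` returns a `GRanges` with `mapq` (and `name`)
#'   metadata columns.
#' @export
read_tagalign <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6])
  if (any(dt$start >= dt$end)) {
    bad <- which(dt$start >= dt$end)[1]
    stop_usage("start >= end at line ", bad, " of ", path)
  }
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(dt$start + 1L, dt$end),
                         strand = dt$strand,
                         mapq = as.integer(dt$score),
                         name = as.character(dt$name))
}

#' @rdname read_tagalign
#' @export
write_tagalign <- function(tags, path) {
  data.table::fwrite(tags_to_dt(tags), path, sep = "\t", col.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read and write BED intervals
#'
#' Reads 3-6 column BED into a `GRanges` (1-based internally; 0-based
#' half-open on disk). `track` and `#` comment lines are skipped; rows
#' with `start >= end` raise an error naming the offending line.
#'
#' @param path File path.
#' @param x A `GRanges`; `name`/`score` metadata columns are written when
#'   present, and strand when any is not `*`.
#' @return `read_bed()` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) return(GenomicRanges::GRanges())
  dt <- data.table::fread(text = lines[keep], header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop_usage("BED file needs >= 3 columns: ", path)
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (any(dt$start >= dt$end)) {
    bad <- which(dt$start >= dt$end)[1]
    stop_usage("start >= end at data line ", bad, " of ", path)
  }
  gr <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end),
    strand = if (ncol(dt) >= 6L) dt[[6]] else "*"
  )
  if (ncol(dt) >= 4L) gr$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) gr$score <- dt[[5]]
  gr
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x)
  )
  has_strand <- any(as.character(GenomicRanges::strand(x)) != "*")
  if (!is.null(x$name) || !is.null(x$score) || has_strand) {
    dt$name <- if (!is.null(x$name)) x$name else "."
  }
  if (!is.null(x$score) || has_strand) {
    dt$score <- if (!is.null(x$score)) x$score else 0
  }
  if (has_strand) dt$strand <- as.character(GenomicRanges::strand(x))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Emits the scaled track (per-base coverage times the reads-per-ten-million
#' scale factor) as sorted 4-column bedGraph; adjacent equal-value runs are
#' merged and zero-valued runs are omitted.
#'
#' @param track A [make_coverage()] track.
#' @param path File path.
#' @param digits Significant digits written for the value column.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 10L) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (is.na(track$scale_factor)) return(invisible(path))  # flagged empty track
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    v <- S4Vectors::runValue(r) * track$scale_factor
    w <- S4Vectors::runLength(r)
    ends <- cumsum(w)
    starts <- ends - w       # 0-based starts
    keep <- v != 0
    if (!any(keep)) next
    writeLines(paste(chrom, starts[keep], ends[keep],
                     formatC(v[keep], digits = digits, format = "g")),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file back into per-chromosome Rle values
#'
#' @param path File path.
#' @param chrom_lengths Optional named lengths used to pad trailing zeros.
#' @return A named list of numeric `Rle`, one per chromosome.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = " ",
                          col.names = c("chrom", "start", "end", "value"))
  out <- list()
  for (chrom in unique(dt$chrom)) {
    d <- dt[dt$chrom == chrom, ]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else max(d$end)
    vals <- numeric(len)
    for (i in seq_len(nrow(d))) vals[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    out[[chrom]] <- S4Vectors::Rle(vals)
  }
  out
}

#' Read and write the gene-by-sample counts table
#'
#' The on-disk format is a TSV with columns `gene`, `gc_fraction`, then one
#' column per sample. A sample sheet (`sample`, `state`, `replicate`) maps
#' samples to states.
#'
#' @param path,counts_path,samples_path File paths.
#' @param em An `expr_matrix` (see [simulate_expression()]).
#' @return `read_expr_matrix()` returns an `expr_matrix`.
#' @export
write_expr_matrix <- function(em, counts_path, samples_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  dt <- data.table::data.table(gene = em$genes$gene,
                               gc_fraction = em$genes$gc_fraction)
  for (s in colnames(em$counts)) dt[[s]] <- em$counts[, s]
  data.table::fwrite(dt, counts_path, sep = "\t", quote = FALSE, eol = "\n")
  if (!is.null(samples_path)) {
    data.table::fwrite(em$samples, samples_path, sep = "\t", quote = FALSE,
                       eol = "\n")
  }
  invisible(counts_path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(counts_path, samples_path) {
  dt <- data.table::fread(counts_path, sep = "\t")
  samples <- as.data.frame(data.table::fread(samples_path, sep = "\t"))
  mat <- as.matrix(dt[, -(1:2)])
  rownames(mat) <- dt$gene
  if (!all(samples$sample %in% colnames(mat))) {
    stop_usage("sample sheet names samples missing from the counts table")
  }
  new_expr_matrix(mat[, samples$sample, drop = FALSE],
                  data.frame(gene = dt$gene, gc_fraction = dt$gc_fraction),
                  samples)
}
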