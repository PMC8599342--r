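#' Generate a synthetic genome
#'
#' Emits one i.i.d. random DNA sequence per configured chromosome at the
#' configured GC fraction, plus a mitochondrial chromosome literally named
#' `chrM` (mitochondrial filtering downstream is name-based). Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A named `DNAStringSet`; the last sequence is `chrM`.
#' @export
#' @examples
#' g <- generate_genome(sim_config(seed = 1))
#' names(g)
generate_genome <- function(config) {
  validate_sim_config(config)
  lengths <- c(config$chrom_lengths, chrM = as.integer(config$chrm_length))
  gc <- config$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(derive_seed(config$seed, 1L), {
    seqs <- vapply(lengths, function(len) {
      paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

region_classes <- c("A_specific", "B_specific", "shared")

#' Plant a two-state regulatory landscape into a genome
#'
#' Lays out non-overlapping accessible regions of three classes
#' (A-specific, B-specific, shared) on the nuclear chromosomes, plants PWM
#' instances into region centres (one base sampled per PWM column, so
#' instances vary around the consensus), writes the instances into the
#' genome sequence, and builds the truth table: planted regions and
#' instances, the differential-gene classes with their true log2 fold
#' changes, TSS positions, and the TF-gene-to-motif links.
#'
#' Target and decoy motifs are planted in A-specific regions with
#' `plant_prob_target`; every other motif-region combination uses
#' `plant_prob_background`. Target-TF genes carry `tf_lfc`; decoy-TF genes
#' stay null (enriched motif without differential expression).
#'
#' @param genome A [generate_genome()] `DNAStringSet`.
#' @param motifs Named list of [pwm_from_counts()] objects.
#' @param config A [sim_config()].
#' @return A list with the edited `genome` and the `truth` table (class
#'   `truth_table`: `regions` GRanges with a `class` column, `instances`
#'   data.frame, `genes` data.frame, `tf_gene_links`, `tss` GRanges,
#'   `seed`).
#' @export
plant_regulatory_landscape <- function(genome, motifs, config) {
  validate_sim_config(config)
  if (!length(motifs)) stop_usage("motifs must be non-empty")
  unknown <- setdiff(c(config$target_motifs, config$decoy_motifs), names(motifs))
  if (length(unknown)) {
    stop_usage("configured motifs absent from library: ", paste(unknown, collapse = ", "))
  }
  nuclear <- setdiff(names(genome), "chrM")
  width <- config$region_width
  spacing <- 2L * width
  n_total <- sum(config$n_regions)

  with_seed(derive_seed(config$seed, 2L), {
    slots <- do.call(rbind, lapply(nuclear, function(chrom) {
      k <- length(genome[[chrom]]) %/% spacing
      if (k < 1L) return(NULL)
      data.frame(chrom = chrom, slot_start = (seq_len(k) - 1L) * spacing + 1L)
    }))
    if (is.null(slots) || nrow(slots) < n_total) {
      stop_usage("insufficient genome space: need ", n_total,
                 " region slots, have ", if (is.null(slots)) 0L else nrow(slots))
    }
    pick <- slots[sample(nrow(slots), n_total), , drop = FALSE]
    cls <- sample(rep(region_classes, config$n_regions[region_classes]))
    starts <- pick$slot_start + sample.int(spacing - width + 1L, n_total,
                                           replace = TRUE) - 1L
    regions <- GenomicRanges::GRanges(
      pick$chrom, IRanges::IRanges(starts, width = width), class = cls,
      name = sprintf("region_%03d", seq_len(n_total))
    )
    regions <- GenomicRanges::sort(regions, ignore.strand = TRUE)

    # plant motif instances in the central portion of each region (motifs
    # concentrate at accessibility summits), non-overlapping within a region
    planted <- list()
    half_core <- min(100L, width %/% 2L)
    for (i in seq_along(regions)) {
      r_cls <- regions$class[i]
      centre <- (GenomicRanges::start(regions)[i] +
                   GenomicRanges::end(regions)[i]) %/% 2L
      occupied <- IRanges::IRanges()
      for (m in names(motifs)) {
        p <- if (r_cls == "A_specific" &&
                 m %in% c(config$target_motifs, config$decoy_motifs)) {
          config$plant_prob_target
        } else {
          config$plant_prob_background
        }
        if (p == 0 || stats::runif(1) >= p) next
        pw <- motifs[[m]]
        inst <- sample_pwm_instance(pw)
        strand <- sample(c("+", "-"), 1L)
        written <- if (strand == "+") inst else {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(inst)))
        }
        lo <- max(GenomicRanges::start(regions)[i], centre - half_core)
        hi <- min(GenomicRanges::end(regions)[i], centre + half_core) - pw$width + 1L
        if (hi < lo) next
        pos <- NA_integer_
        for (try in 1:200) {
          cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          cand_rng <- IRanges::IRanges(cand, width = pw$width)
          if (!length(IRanges::findOverlaps(cand_rng, occupied))) {
            pos <- cand
            occupied <- c(occupied, cand_rng)
            break
          }
        }
        if (is.na(pos)) next   # could not place without clobbering another instance
        planted[[length(planted) + 1L]] <- data.frame(
          motif = m, region = regions$name[i], region_class = r_cls,
          chrom = as.character(GenomicRanges::seqnames(regions))[i],
          start = pos, end = pos + pw$width - 1L, strand = strand,
          instance = inst, written = written
        )
      }
    }
    instances <- if (length(planted)) do.call(rbind, planted) else {
      data.frame(motif = character(0), region = character(0),
                 region_class = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 instance = character(0), written = character(0))
    }

    for (chrom in unique(instances$chrom)) {
      d <- instances[instances$chrom == chrom, , drop = FALSE]
      genome[[chrom]] <- Biostrings::replaceAt(
        genome[[chrom]], IRanges::IRanges(d$start, d$end), d$written)
    }

    # differential-gene truth: planted A-high / B-high genes plus one TF
    # gene per library motif, target TFs truly A-high, decoys null
    gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
    cls_gene <- rep("null", config$n_genes)
    lfc <- rep(0, config$n_genes)
    de_idx <- sample(config$n_genes,
                     config$n_de_genes[["A_high"]] + config$n_de_genes[["B_high"]])
    a_idx <- de_idx[seq_len(config$n_de_genes[["A_high"]])]
    b_idx <- setdiff(de_idx, a_idx)
    cls_gene[a_idx] <- "A_high"; lfc[a_idx] <- config$de_lfc
    cls_gene[b_idx] <- "B_high"; lfc[b_idx] <- -config$de_lfc
    tf_genes <- names(motifs)
    tf_cls <- ifelse(tf_genes %in% config$target_motifs, "A_high", "null")
    tf_lfc <- ifelse(tf_genes %in% config$target_motifs, config$tf_lfc, 0)
    genes <- data.frame(
      gene = c(gene_ids, tf_genes),
      class = c(cls_gene, tf_cls),
      true_lfc = c(lfc, tf_lfc),
      is_tf = c(rep(FALSE, config$n_genes), rep(TRUE, length(tf_genes)))
    )
    tf_gene_links <- data.frame(tf_gene = tf_genes, motif = tf_genes)

    # TSS annotation: TF genes sit near a region of the class their motif
    # is planted in; all other genes are uniform over the nuclear genome
    chrom_w <- config$chrom_lengths[nuclear]
    tss_chrom <- sample(nuclear, nrow(genes), replace = TRUE,
                        prob = chrom_w / sum(chrom_w))
    tss_pos <- vapply(tss_chrom, function(ch) {
      sample.int(config$chrom_lengths[[ch]], 1L)
    }, integer(1))
    a_regions <- regions[regions$class == "A_specific"]
    for (i in which(genes$is_tf & genes$gene %in%
                    c(config$target_motifs, config$decoy_motifs))) {
      if (!length(a_regions)) break
      r <- a_regions[sample(length(a_regions), 1L)]
      tss_chrom[i] <- as.character(GenomicRanges::seqnames(r))
      tss_pos[i] <- min(GenomicRanges::end(r) + sample(100:2000, 1L),
                        config$chrom_lengths[[tss_chrom[i]]])
    }
    tss <- GenomicRanges::GRanges(tss_chrom,
                                  IRanges::IRanges(tss_pos, width = 1L),
                                  strand = sample(c("+", "-"), nrow(genes),
                                                  replace = TRUE),
                                  gene = genes$gene)

    truth <- structure(
      list(regions = regions, instances = instances, genes = genes,
           tf_gene_links = tf_gene_links, tss = tss, seed = config$seed,
           region_width = width),
      class = "truth_table")
    list(genome = genome, truth = truth)
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table: ", length(x$regions), " regions (",
      paste(names(table(x$regions$class)), table(x$regions$class),
            sep = "=", collapse = ", "),
      "), ", nrow(x$instances), " planted instances, ",
      nrow(x$genes), " genes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

open_regions_for_state <- function(truth, state_index) {
  cls <- if (state_index == 1L) c("A_specific", "shared") else c("B_specific", "shared")
  truth$regions[truth$regions$class %in% cls]
}

#' Simulate per-replicate ATAC tag libraries
#'
#' Generates tag alignments for each state and replicate. A configured
#' fraction of tags falls on `chrM`; the rest are placed on the nuclear
#' genome with per-base density `enrichment`-fold higher inside the
#' regions open in that state (state-specific plus shared) than in the
#' background. Configured fractions of exact duplicates (same chromosome,
#' position and strand) and of tags with mapping quality below 35 are
#' added. Replicates differ only by their derived random stream.
#'
#' @param truth A [plant_regulatory_landscape()] truth table.
#' @param genome The matching `DNAStringSet`.
#' @param config A [sim_config()].
#' @return A nested list `tags[[state]][[replicate]]` of `GRanges` with a
#'   `mapq` metadata column.
#' @export
simulate_atac_tags <- function(truth, genome, config) {
  validate_sim_config(config)
  lens <- stats::setNames(lengths(genome), names(genome))
  if (config$tags_per_replicate == 0L) {
    warning("zero requested depth: returning empty tag sets")
    empty <- GenomicRanges::GRanges(seqlengths = lens)
    empty$mapq <- integer(0)
    out <- lapply(config$states, function(s) {
      stats::setNames(rep(list(empty), config$n_replicates),
                      paste0("rep", seq_len(config$n_replicates)))
    })
    return(stats::setNames(out, config$states))
  }
  nuclear <- setdiff(names(genome), "chrM")
  taglen <- config$tag_length
  with_seed(derive_seed(config$seed, 3L), {
    out <- list()
    for (si in seq_along(config$states)) {
      state <- config$states[si]
      open <- open_regions_for_state(truth, si)
      l_open <- sum(GenomicRanges::width(open))
      l_nuc <- sum(lens[nuclear])
      bg <- GenomicRanges::setdiff(
        GenomicRanges::GRanges(nuclear, IRanges::IRanges(1L, lens[nuclear])),
        open, ignore.strand = TRUE)
      p_sig <- config$enrichment * l_open /
        (config$enrichment * l_open + (l_nuc - l_open))
      reps <- list()
      for (r in seq_len(config$n_replicates)) {
        n <- config$tags_per_replicate
        n_dup <- round(n * config$dup_rate)
        n_base <- n - n_dup
        # category per tag: mitochondrial, signal (open region) or background
        is_chrm <- stats::runif(n_base) < config$chrm_rate
        cat <- ifelse(is_chrm, "M",
                      ifelse(stats::runif(n_base) < p_sig & length(open) > 0,
                             "S", "B"))
        place <- function(pool, k) {
          w <- pmax(GenomicRanges::width(pool) - taglen + 1L, 0L)
          j <- sample(length(pool), k, replace = TRUE, prob = w)
          list(chrom = as.character(GenomicRanges::seqnames(pool))[j],
               start = GenomicRanges::start(pool)[j] +
                 floor(stats::runif(k) * w[j]))
        }
        draw <- function(idx, chrom, start) {
          for (cc in c("M", "S", "B")) {
            i <- idx[cat[idx] == cc]
            if (!length(i)) next
            if (cc == "M") {
              chrom[i] <- "chrM"
              start[i] <- sample.int(max(lens[["chrM"]] - taglen + 1L, 1L),
                                     length(i), replace = TRUE)
            } else {
              p <- place(if (cc == "S") open else bg, length(i))
              chrom[i] <- p$chrom
              start[i] <- p$start
            }
          }
          list(chrom = chrom, start = start)
        }
        strand <- sample(c("+", "-"), n_base, replace = TRUE)
        d <- draw(seq_len(n_base), character(n_base), integer(n_base))
        chrom <- d$chrom; start <- d$start
        # base tags are unique by construction: only dup_rate plants exact
        # (chrom, position, strand) copies; chance collisions are redrawn
        # within their category
        for (iter in 1:50) {
          dup <- which(duplicated(paste(chrom, start, strand, sep = "\r")))
          if (!length(dup)) break
          d <- draw(dup, chrom, start)
          chrom <- d$chrom; start <- d$start
        }
        low <- stats::runif(n_base) < config$low_mapq_rate
        mapq <- ifelse(low, sample(0:34, n_base, replace = TRUE), 60L)
        if (n_dup > 0L) {
          j <- sample.int(n_base, n_dup, replace = TRUE)
          chrom <- c(chrom, chrom[j]); start <- c(start, start[j])
          strand <- c(strand, strand[j]); mapq <- c(mapq, mapq[j])
        }
        gr <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(start, width = taglen), strand = strand,
          mapq = as.integer(mapq),
          name = sprintf("%s_rep%d_tag%06d", state, r, seq_along(chrom)),
          seqlengths = lens)
        reps[[paste0("rep", r)]] <- GenomicRanges::trim(gr)
      }
      out[[state]] <- reps
    }
    out
  })
}

new_expr_matrix <- function(counts, genes, samples, normalized = FALSE) {
  stopifnot(is.matrix(counts), nrow(counts) == nrow(genes),
            ncol(counts) == nrow(samples))
  if (any(counts < 0)) stop_usage("expression matrix has negative values")
  if (any(is.na(genes$gc_fraction))) stop_usage("GC fraction undefined for some genes")
  if (any(is.na(samples$state))) stop_usage("every sample must map to a state")
  structure(list(counts = counts, genes = genes, samples = samples,
                 normalized = normalized),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (states: ",
      paste(unique(x$samples$state), collapse = ", "), ")",
      if (x$normalized) ", GC-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Simulate the gene-by-sample count matrix
#'
#' Draws negative-binomial counts around per-gene state means. Each gene
#' gets a baseline mean (lognormal) and a GC fraction; genes planted as
#' A-high or B-high in the truth table have their high-state mean raised
#' by `2^|true_lfc|`, and a multiplicative GC bias
#' `2^(gc_bias_slope * (gc - 0.5))` is applied in every sample.
#'
#' @param truth A truth table from [plant_regulatory_landscape()].
#' @param config A [sim_config()].
#' @return An `expr_matrix`: `counts` (genes x samples), `genes`
#'   (`gene`, `gc_fraction`), `samples` (`sample`, `state`, `replicate`).
#' @export
simulate_expression <- function(truth, config) {
  validate_sim_config(config)
  if (config$dispersion <= 0) stop_usage("dispersion must be positive")
  g <- truth$genes
  n <- nrow(g)
  with_seed(derive_seed(config$seed, 4L), {
    gc <- stats::runif(n, 0.3, 0.7)
    base <- stats::rlnorm(n, config$base_mean_log_mean, config$base_mean_log_sd)
    mu_a <- base * 2^pmax(g$true_lfc, 0)
    mu_b <- base * 2^pmax(-g$true_lfc, 0)
    bias <- 2^(config$gc_bias_slope * (gc - 0.5))
    samples <- expand.grid(replicate = seq_len(config$n_expr_replicates),
                           state = config$states,
                           stringsAsFactors = FALSE)[, c("state", "replicate")]
    samples$sample <- paste0(samples$state, "_rep", samples$replicate)
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      mu <- if (samples$state[j] == config$states[1]) mu_a else mu_b
      stats::rnbinom(n, mu = mu * bias, size = config$dispersion)
    }, numeric(n))
    counts <- matrix(counts, nrow = n)
    colnames(counts) <- samples$sample
    rownames(counts) <- g$gene
    new_expr_matrix(counts,
                    data.frame(gene = g$gene, gc_fraction = gc),
                    samples[, c("sample", "state", "replicate")])
  })
}

#' Write / read the truth table as JSON
#'
#' Intervals are serialized 0-based half-open (BED convention); reading
#' restores the in-memory 1-based `GRanges` representation.
#'
#' @param truth A `truth_table`.
#' @param path File path.
#' @return `read_truth_table()` returns a `truth_table`.
#' @export
write_truth_table <- function(truth, path) {
  r <- truth$regions
  obj <- list(
    seed = truth$seed,
    region_width = truth$region_width,
    regions = data.frame(chrom = as.character(GenomicRanges::seqnames(r)),
                         start = GenomicRanges::start(r) - 1L,
                         end = GenomicRanges::end(r),
                         class = r$class, name = r$name),
    instances = within(truth$instances, start <- start - 1L),
    genes = truth$genes,
    tf_gene_links = truth$tf_gene_links,
    tss = data.frame(chrom = as.character(GenomicRanges::seqnames(truth$tss)),
                     pos = GenomicRanges::start(truth$tss) - 1L,
                     strand = as.character(GenomicRanges::strand(truth$tss)),
                     gene = truth$tss$gene)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    regions = GenomicRanges::GRanges(
      obj$regions$chrom,
      IRanges::IRanges(obj$regions$start + 1L, obj$regions$end),
      class = obj$regions$class, name = obj$regions$name),
    instances = within(obj$instances, start <- start + 1L),
    genes = obj$genes,
    tf_gene_links = obj$tf_gene_links,
    tss = GenomicRanges::GRanges(
      obj$tss$chrom, IRanges::IRanges(obj$tss$pos + 1L, width = 1L),
      strand = obj$tss$strand, gene = obj$tss$gene),
    seed = obj$seed, region_width = obj$region_width),
    class = "truth_table")
}

#' Simulate the complete two-state landscape
#'
#' Convenience wrapper: genome, planted landscape, ATAC tag libraries and
#' count matrix in one call.
#'
#' @param config A [sim_config()].
#' @param motifs Motif library (defaults to the shipped one).
#' @return List with `genome`, `truth`, `tags`, `expr`.
#' @export
simulate_landscape <- function(config = sim_config(), motifs = motif_library()) {
  genome <- generate_genome(config)
  pl <- plant_regulatory_landscape(genome, motifs, config)
  tags <- simulate_atac_tags(pl$truth, pl$genome, config)
  expr <- simulate_expression(pl$truth, config)
  list(genome = pl$genome, truth = pl$truth, tags = tags, expr = expr)
}
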