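test_that("generated genomes have configured geometry, GC content and are reproducible", {
  cfg <- sim_config(chrom_lengths = c(chrA = 50000L, chrB = 50000L),
                    chrm_length = 1000L, seed = 1)
  g <- generate_genome(cfg)
  expect_named(g, c("chrA", "chrB", "chrM"))
  expect_equal(sum(lengths(g)), 101000L)
  expect_true(all(lengths(g) > 0))

  g2 <- generate_genome(cfg)
  expect_identical(as.character(g), as.character(g2))

  cfg_gc <- sim_config(chrom_lengths = c(chr1 = 100000L), gc_content = 0.6,
                       seed = 1)
  gg <- generate_genome(cfg_gc)
  freq <- Biostrings::alphabetFrequency(gg[["chr1"]])
  gc_obs <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  expect_gt(gc_obs, 0.55)
  expect_lt(gc_obs, 0.65)
  expect_true(all(Biostrings::alphabetFrequency(gg[["chr1"]])[-(1:4)] == 0))
})

test_that("planting honours probabilities and records a closed truth table", {
  motifs <- motif_library()
  # probability-1 planting: every A-specific region carries the motif
  cfg <- sim_config(n_regions = c(A_specific = 30L, B_specific = 10L, shared = 10L),
                    target_motifs = "TEAD2", decoy_motifs = character(0),
                    plant_prob_target = 1, plant_prob_background = 0.05,
                    seed = 3)
  pl <- plant_regulatory_landscape(generate_genome(cfg), motifs, cfg)
  inst_a <- pl$truth$instances[pl$truth$instances$motif == "TEAD2" &
                               pl$truth$instances$region_class == "A_specific", ]
  expect_equal(length(unique(inst_a$region)), 30L)

  # zero planting probability leaves no instances
  cfg0 <- sim_config(plant_prob_target = 0, plant_prob_background = 0, seed = 3)
  pl0 <- plant_regulatory_landscape(generate_genome(cfg0), motifs, cfg0)
  expect_equal(nrow(pl0$truth$instances), 0L)

  # truth-table closure: every instance is retrievable from the emitted
  # genome sequence at its recorded coordinates
  inst <- pl$truth$instances
  for (i in seq_len(nrow(inst))) {
    got <- as.character(Biostrings::extractAt(
      pl$genome[[inst$chrom[i]]],
      IRanges::IRanges(inst$start[i], inst$end[i])))
    expect_identical(got, inst$written[i])
  }

  # class exclusivity: no base belongs to two classes
  expect_true(IRanges::isDisjoint(pl$truth$regions))
})

test_that("planted-instance counts are binomially plausible and match a truth recount", {
  motifs <- motif_library()
  cfg <- sim_config(n_regions = c(A_specific = 50L, B_specific = 50L, shared = 50L),
                    target_motifs = "TEAD2", decoy_motifs = character(0),
                    plant_prob_target = 0.8, plant_prob_background = 0.05,
                    seed = 7)
  pl <- plant_regulatory_landscape(generate_genome(cfg), motifs, cfg)
  inst <- pl$truth$instances
  k <- sum(inst$motif == "TEAD2" & inst$region_class == "A_specific")
  # direct recount of truth-table entries, region by region
  a_regions <- pl$truth$regions$name[pl$truth$regions$class == "A_specific"]
  recount <- sum(vapply(a_regions, function(r) {
    any(inst$region == r & inst$motif == "TEAD2")
  }, logical(1)))
  expect_equal(k, recount)
  expect_gte(binom.test(k, 50, 0.8)$p.value, 0.01)
})

test_that("planting fails loudly when the genome cannot host the regions", {
  motifs <- motif_library()
  cfg <- sim_config(chrom_lengths = c(chr1 = 20000L),
                    n_regions = c(A_specific = 50L, B_specific = 50L, shared = 50L),
                    seed = 1)
  expect_error(plant_regulatory_landscape(generate_genome(cfg), motifs, cfg),
               "insufficient genome space")
})

test_that("simulated tags carry the configured contamination and enrichment", {
  motifs <- motif_library()
  # no contaminants: the filter chain removes nothing
  cfg0 <- sim_config(dup_rate = 0, chrm_rate = 0, low_mapq_rate = 0, seed = 5)
  pl0 <- plant_regulatory_landscape(generate_genome(cfg0), motifs, cfg0)
  tags0 <- simulate_atac_tags(pl0$truth, pl0$genome, cfg0)
  t1 <- tags0[[cfg0$states[1]]]$rep1
  expect_equal(length(filter_tags(t1)), length(t1))

  # chrM contamination within the exact binomial 99% interval
  cfgm <- sim_config(chrm_rate = 0.3, dup_rate = 0, low_mapq_rate = 0,
                     tags_per_replicate = 10000L, seed = 11)
  plm <- plant_regulatory_landscape(generate_genome(cfgm), motifs, cfgm)
  tm <- simulate_atac_tags(plm$truth, plm$genome, cfgm)[[cfgm$states[1]]]$rep1
  n_chrm <- sum(as.character(GenomicRanges::seqnames(tm)) == "chrM")
  bounds <- qbinom(c(0.005, 0.995), 10000L, 0.3)
  expect_gte(n_chrm, bounds[1])
  expect_lte(n_chrm, bounds[2])

  # signal regions at ~5% of the genome, 10x enrichment: the fraction of
  # tags inside signal regions, recounted from the emitted tags, matches
  # the configured expectation within exact binomial bounds
  cfgs <- sim_config(chrom_lengths = c(chr1 = 100000L, chr2 = 100000L),
                     n_regions = c(A_specific = 20L, B_specific = 0L, shared = 0L),
                     dup_rate = 0, chrm_rate = 0, low_mapq_rate = 0,
                     enrichment = 10, seed = 13)
  pls <- plant_regulatory_landscape(generate_genome(cfgs), motifs, cfgs)
  ts <- simulate_atac_tags(pls$truth, pls$genome, cfgs)[[cfgs$states[1]]]$rep1
  open <- pls$truth$regions
  l_open <- sum(GenomicRanges::width(open))
  p_sig <- 10 * l_open / (10 * l_open + (200000 - l_open))
  in_sig <- sum(GenomicRanges::countOverlaps(ts, open, type = "within",
                                             ignore.strand = TRUE) > 0)
  bounds <- qbinom(c(0.005, 0.995), length(ts), p_sig)
  expect_gte(in_sig, bounds[1])
  expect_lte(in_sig, bounds[2])

  # reproducibility and replicate independence
  tags_a <- simulate_atac_tags(pl0$truth, pl0$genome, cfg0)
  expect_identical(tags0, tags_a)
  expect_false(identical(tags0[[cfg0$states[1]]]$rep1,
                         tags0[[cfg0$states[1]]]$rep2))
})

test_that("zero requested tag depth warns and returns empty sets", {
  motifs <- motif_library()
  cfg <- sim_config(seed = 2)
  pl <- plant_regulatory_landscape(generate_genome(cfg), motifs, cfg)
  cfg$tags_per_replicate <- 0L
  expect_warning(tags <- simulate_atac_tags(pl$truth, pl$genome, cfg),
                 "zero requested depth")
  expect_equal(length(tags[[cfg$states[1]]]$rep1), 0L)
})

test_that("expression simulation is null when no effects are planted", {
  truth <- list(genes = data.frame(gene = sprintf("g%03d", 1:200),
                                   class = "null", true_lfc = 0,
                                   is_tf = FALSE))
  cfg <- sim_config(n_genes = 200L, gc_bias_slope = 0, seed = 21)
  em <- simulate_expression(truth, cfg)
  a <- rowMeans(em$counts[, em$samples$sample[em$samples$state == "A"]])
  b <- rowMeans(em$counts[, em$samples$sample[em$samples$state == "B"]])
  expect_gte(t.test(a, b, paired = TRUE)$p.value, 0.01)
})

test_that("a planted log2FC of 3 yields state-mean ratios in [4, 16] almost always", {
  truth <- list(genes = data.frame(gene = "g1", class = "A_high",
                                   true_lfc = 3, is_tf = FALSE))
  ok <- 0L
  for (s in 1:200) {
    cfg <- sim_config(seed = s, n_genes = 1L, base_mean_log_mean = log(100),
                      base_mean_log_sd = 1e-9, dispersion = 10,
                      gc_bias_slope = 0)
    em <- simulate_expression(truth, cfg)
    ma <- mean(em$counts[1, em$samples$sample[em$samples$state == "A"]])
    mb <- mean(em$counts[1, em$samples$sample[em$samples$state == "B"]])
    if (mb > 0 && ma / mb >= 4 && ma / mb <= 16) ok <- ok + 1L
  }
  expect_gte(ok, 190L)  # >= 95% of 200 seeds
})

test_that("with GC bias off, GC and log counts are uncorrelated", {
  truth <- list(genes = data.frame(gene = sprintf("g%04d", 1:2000),
                                   class = "null", true_lfc = 0,
                                   is_tf = FALSE))
  cfg <- sim_config(n_genes = 2000L, gc_bias_slope = 0, seed = 31)
  em <- simulate_expression(truth, cfg)
  for (s in colnames(em$counts)) {
    r <- cor(em$genes$gc_fraction, log2(em$counts[, s] + 1))
    expect_lt(abs(r), 0.1)
  }
})

test_that("the truth table round-trips through JSON", {
  motifs <- motif_library()
  cfg <- sim_config(seed = 17)
  pl <- plant_regulatory_landscape(generate_genome(cfg), motifs, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_table(pl$truth, path)
  back <- read_truth_table(path)
  expect_equal(as.data.frame(back$regions), as.data.frame(pl$truth$regions))
  expect_equal(back$instances, pl$truth$instances)
  expect_equal(back$genes, pl$truth$genes)
  expect_equal(back$seed, pl$truth$seed)
})
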