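make_em <- function(counts, gc, states = c("A", "A", "B", "B"),
                    normalized = FALSE) {
  counts <- as.matrix(counts)
  samples <- data.frame(sample = paste0(states, "_rep",
                                        ave(seq_along(states), states,
                                            FUN = seq_along)),
                        state = states,
                        replicate = ave(seq_along(states), states,
                                        FUN = seq_along))
  colnames(counts) <- samples$sample
  rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  atacscreen:::new_expr_matrix(counts,
                               data.frame(gene = rownames(counts),
                                          gc_fraction = gc),
                               samples, normalized = normalized)
}

test_that("GC normalization is a no-op (up to a constant) without a GC effect", {
  set.seed(71)
  n <- 500
  gc <- runif(n, 0.3, 0.7)
  base <- rep(100, n)                      # identical within every GC bin
  counts <- cbind(base, base * 2, base, base)
  em <- make_em(counts, gc)
  norm <- gc_normalize(em, upper_quartile = TRUE)
  for (j in 1:4) {
    ratio <- norm$counts[, j] / em$counts[, j]
    expect_lt(diff(range(ratio)), 1e-12)    # single global constant per sample
  }
  # and the upper-quartile step has equalized the samples
  expect_equal(norm$counts[, 1], norm$counts[, 2], ignore_attr = TRUE)
})

test_that("GC normalization removes a planted monotone bias", {
  motifs <- motif_library()
  cfg <- sim_config(seed = 73)  # default gc_bias_slope = 3
  pl <- plant_regulatory_landscape(generate_genome(cfg), motifs, cfg)
  em <- simulate_expression(pl$truth, cfg)
  norm <- gc_normalize(em)
  for (s in colnames(norm$counts)) {
    rho <- cor(norm$genes$gc_fraction, log2(norm$counts[, s] + 1),
               method = "spearman")
    expect_lt(abs(rho), 0.1)
  }
})

test_that("GC normalization is scale-invariant across samples and idempotent", {
  set.seed(72)
  n <- 1000
  gc <- runif(n, 0.3, 0.7)
  base <- rnbinom(n, mu = 100 * 2^(2 * (gc - 0.5)), size = 20)
  counts <- cbind(base, 2 * base, base + rpois(n, 5), base)
  em <- make_em(counts, gc)
  norm <- gc_normalize(em, upper_quartile = TRUE)
  rel <- abs(norm$counts[, 2] - norm$counts[, 1]) /
    pmax(norm$counts[, 1], 1e-12)
  expect_lt(max(rel[norm$counts[, 1] > 0]), 1e-6)
  expect_true(all(norm$counts[em$counts == 0] == 0))  # zeros stay zero

  twice <- gc_normalize(norm, upper_quartile = TRUE)
  rel2 <- abs(twice$counts - norm$counts) / pmax(norm$counts, 1e-12)
  expect_lt(max(rel2[norm$counts > 0]), 1e-6)
})

test_that("degenerate all-zero GC bins are skipped with a warning", {
  set.seed(74)
  gc <- c(runif(50, 0.30, 0.35), runif(50, 0.60, 0.70))
  counts <- cbind(c(rep(0, 50), rpois(50, 100)),
                  c(rep(0, 50), rpois(50, 100)),
                  c(rep(0, 50), rpois(50, 100)),
                  c(rep(0, 50), rpois(50, 100)))
  em <- make_em(counts, gc)
  w <- capture_warnings(gc_normalize(em, n_bins = 4, upper_quartile = FALSE))
  expect_length(w, 4L)   # one per sample
  expect_true(all(grepl("degenerate GC bin", w)))
})

test_that("replicate means and SEMs follow the textbook formulas", {
  em <- make_em(cbind(c(10, 5), c(14, 7), c(1, 1), c(3, 3)),
                gc = c(0.4, 0.5))
  rm_a <- replicate_mean(em, "A")
  expect_equal(rm_a$mean, c(12, 6))
  expect_equal(rm_a$sem, c(2, 1))
  expect_true(attr(rm_a, "sem_defined"))

  single <- make_em(cbind(c(10, 5)), gc = c(0.4, 0.5), states = "A")
  rm_s <- replicate_mean(single, "A")
  expect_equal(rm_s$mean, c(10, 5))
  expect_equal(rm_s$sem, c(0, 0))
  expect_false(attr(rm_s, "sem_defined"))
  expect_error(replicate_mean(em, "Z"), "unknown state")

  set.seed(75)
  counts <- matrix(rpois(400, 50), 100, 4)
  em2 <- make_em(counts, gc = runif(100, 0.3, 0.7))
  rm2 <- replicate_mean(em2, "B")
  expect_equal(rm2$mean, rowMeans(counts[, 3:4]))
  expect_equal(rm2$sem, apply(counts[, 3:4], 1, sd) / sqrt(2))
})

test_that("highly expressed gene calls follow the fold/abundance rule", {
  em <- make_em(cbind(c(100, 100), c(100, 100), c(10, 100), c(10, 100)),
                gc = c(0.4, 0.5), normalized = TRUE)
  calls <- classify_highly_expressed(em, "A", "B", min_fc = 2, min_expr = 50)
  expect_equal(calls$class, c("A_high", "null"))
  expect_equal(calls$log2fc[1], log2(10), tolerance = 0.2)
  expect_equal(calls$log2fc[2], 0, tolerance = 1e-12)
  expect_error(classify_highly_expressed(em, "A", "B", min_fc = 0.5),
               "min_fc")
})

test_that("classification is monotone in its thresholds and classes are disjoint", {
  set.seed(76)
  counts <- matrix(rnbinom(4000, mu = 80, size = 5), 1000, 4)
  em <- make_em(counts, gc = runif(1000, 0.3, 0.7), normalized = TRUE)
  n_specific <- function(min_fc, min_expr) {
    calls <- classify_highly_expressed(em, "A", "B", min_fc, min_expr)
    expect_equal(sum(calls$class == "A_high" & calls$class == "B_high"), 0L)
    sum(calls$class != "null")
  }
  by_fc <- vapply(c(1.2, 1.5, 2, 3, 5), n_specific, integer(1), min_expr = 10)
  expect_true(!is.unsorted(rev(by_fc)))
  by_expr <- vapply(c(0, 10, 30, 100), function(e) n_specific(1.5, e), integer(1))
  expect_true(!is.unsorted(rev(by_expr)))
})

test_that("planted differential genes are recovered with low false discovery", {
  truth <- list(genes = data.frame(
    gene = sprintf("g%04d", 1:2000),
    class = c(rep("A_high", 200), rep("null", 1800)),
    true_lfc = c(rep(3, 200), rep(0, 1800)),
    is_tf = FALSE))
  cfg <- sim_config(n_genes = 2000L, seed = 77)
  em <- gc_normalize(simulate_expression(truth, cfg))
  calls <- classify_highly_expressed(em, "A", "B")
  called_a <- calls$gene[calls$class == "A_high"]
  true_a <- truth$genes$gene[truth$genes$class == "A_high"]
  recall <- mean(true_a %in% called_a)
  fdp <- if (length(called_a)) mean(!called_a %in% true_a) else 0
  expect_gte(recall, 0.95)
  expect_lte(fdp, 0.10)
})

test_that("the pooled t test matches its closed form and handles degeneracy", {
  em <- make_em(cbind(c(8), c(12), c(28), c(32)), gc = 0.5, normalized = TRUE)
  res <- tf_expression_test(em, "g0001", "A", "B", alpha = 0.05)
  oracle <- oracle_pooled_t(c(8, 12), c(28, 32))
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$t, -20 / sqrt(8), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$class, "B_high")
  expect_true(res$low_power)

  # identical groups: t = 0, p = 1
  em0 <- make_em(cbind(10, 10, 10, 10), gc = 0.5, normalized = TRUE)
  res0 <- tf_expression_test(em0, "g0001", "A", "B")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # zero variance, unequal means: p -> 0, flagged
  emz <- make_em(cbind(10, 10, 20, 20), gc = 0.5, normalized = TRUE)
  expect_warning(resz <- tf_expression_test(emz, "g0001", "A", "B"),
                 "zero variance")
  expect_equal(resz$p, 0)
})

test_that("permuting group labels flips t and keeps p", {
  em <- make_em(cbind(5, 9, 14, 20), gc = 0.5, normalized = TRUE)
  ab <- tf_expression_test(em, "g0001", "A", "B")
  ba <- tf_expression_test(em, "g0001", "B", "A")
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("the t statistic agrees with the independent formula on random inputs", {
  set.seed(78)
  for (i in 1:100) {
    x <- rnorm(sample(2:6, 1), 10, 3)
    y <- rnorm(sample(2:6, 1), 12, 3)
    em <- make_em(matrix(c(x, y), nrow = 1),
                  gc = 0.5,
                  states = c(rep("A", length(x)), rep("B", length(y))),
                  normalized = TRUE)
    res <- tf_expression_test(em, "g0001", "A", "B")
    oracle <- oracle_pooled_t(x, y)
    expect_equal(res$t, oracle$t, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
  }
})
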