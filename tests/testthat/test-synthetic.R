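# Synthetic panel generator: bookkeeping, determinism, planted structure.

small_config <- function(seed = 7L, ...) {
  synthetic_panel_config(n_reference = 60, n_group = 4, n_genes = 200,
                         n_common = 10, n_group_selective = 8,
                         n_reference_selective = 4,
                         n_mutation_features = 10, n_lineages = 8,
                         seed = seed, ...)
}

test_that("panel dimensions and truth-table sizes match the config", {
  cf <- small_config()
  p <- simulate_panel(cf)
  expect_equal(dim(p$gene_effect$values), c(64, 200))
  expect_equal(dim(p$dependency_probability$values), c(64, 200))
  expect_equal(sum(p$truth$genes$class == "group_selective"), 8)
  expect_equal(sum(p$truth$genes$class == "common_essential"), 10)
  expect_equal(sum(p$truth$genes$class == "reference_selective"), 4)
  expect_equal(nrow(p$truth$biomarkers), 2)
  expect_length(p$truth$isg_genes, 38)
  expect_equal(sum(p$meta$group_flag), 4)
  # truth tables reference existing genes only
  expect_true(all(p$truth$genes$gene %in% colnames(p$gene_effect$values)))
  expect_true(all(p$truth$window$block %in% p$coords$gene_symbol))
  # expression covers panel genes plus the signature
  expect_true(all(p$truth$isg_genes %in% colnames(p$expression$values)))
})

test_that("identical seeds give byte-identical serialized panels", {
  p1 <- simulate_panel(small_config(seed = 13L))
  p2 <- simulate_panel(small_config(seed = 13L))
  d1 <- tempfile(); d2 <- tempfile()
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  p3 <- simulate_panel(small_config(seed = 14L))
  expect_false(identical(p1$gene_effect$values, p3$gene_effect$values))
})

test_that("planted group-selective effects land near the configured mean", {
  cf <- small_config(seed = 21L)
  p <- simulate_panel(cf)
  sel <- p$truth$genes$gene[p$truth$genes$class == "group_selective"]
  grp <- p$meta$group_flag
  for (g in sel) {
    emp <- mean(p$gene_effect$values[grp, g])
    expect_lt(abs(emp - cf$group_effect),
              3 * cf$noise_sd / sqrt(cf$n_group))
  }
  # neutral genes: group-vs-reference difference shrinks with the noise
  quiet <- simulate_panel(small_config(seed = 21L, noise_sd = 1e-4))
  neutral <- quiet$truth$genes$gene[quiet$truth$genes$class == "neutral"][1:20]
  diffs <- abs(colMeans(quiet$gene_effect$values[grp, neutral]) -
                 colMeans(quiet$gene_effect$values[!grp, neutral]))
  expect_lt(max(diffs), 1e-3)
})

test_that("dependency probability is a monotone noisy transform in [0, 1]", {
  p <- simulate_panel(small_config(seed = 3L))
  pr <- p$dependency_probability$values
  ef <- p$gene_effect$values
  expect_true(all(pr >= 0 & pr <= 1))
  # strongly negative effects map near 1, near-zero effects near 0
  expect_gt(mean(pr[ef < -0.9]), 0.9)
  expect_lt(mean(pr[abs(ef) < 0.1]), 0.1)
  expect_gt(cor(as.vector(ef), as.vector(pr)), -1)
  expect_lt(cor(as.vector(ef), as.vector(pr)), -0.7)
})

test_that("copy number is spatially autocorrelated along chromosomes", {
  p <- simulate_panel(small_config(seed = 5L))
  cn <- p$copy_number$values
  coords <- p$coords
  chr1 <- coords$gene_symbol[coords$chromosome == "chr1"]
  adj <- vapply(seq_len(length(chr1) - 1), function(i) {
    cor(cn[, chr1[i]], cn[, chr1[i + 1]])
  }, 0)
  set.seed(1)
  far <- replicate(50, {
    pair <- sample(coords$gene_symbol, 2)
    cor(cn[, pair[1]], cn[, pair[2]])
  })
  expect_gt(mean(adj), mean(far) + 0.3)
  # planted block shares a segment-level signal
  block <- p$truth$window$block
  anchor <- p$truth$window$anchor
  others <- setdiff(block, anchor)
  expect_gt(min(cor(cn[, anchor], cn[, others])), 0.5)
})

test_that("recovery metrics follow the confusion arithmetic", {
  truth <- data.frame(gene = sprintf("G%02d", 1:30),
                      class = c(rep("group_selective", 20),
                                rep("neutral", 10)))
  calls <- data.frame(gene = truth$gene,
                      relaxed_status = c(rep("group_selective", 18),
                                         rep("not_selective", 2),
                                         "group_selective",
                                         rep("not_selective", 9)))
  res <- evaluate_recovery(calls, truth, "relaxed")
  expect_equal(res$sensitivity, 0.9)
  expect_equal(res$precision, 18 / 19)
  expect_equal(res$fp_neutral, 1)
  # perfect calls
  calls2 <- data.frame(gene = truth$gene,
                       relaxed_status = ifelse(truth$class == "group_selective",
                                               "group_selective",
                                               "not_selective"))
  res2 <- evaluate_recovery(calls2, truth, "relaxed")
  expect_equal(res2$sensitivity, 1)
  expect_equal(res2$precision, 1)
  # empty calls
  calls3 <- data.frame(gene = truth$gene, relaxed_status = "not_selective")
  res3 <- evaluate_recovery(calls3, truth, "relaxed")
  expect_equal(res3$sensitivity, 0)
  expect_equal(res3$specificity, 1)
  expect_error(evaluate_recovery(calls3[-1, ], truth, "relaxed"),
               "different gene universes")
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_panel_config(n_genes = 20, n_common = 50),
               "exceed")
  expect_error(synthetic_panel_config(noise_sd = 0), "positive")
  expect_error(synthetic_panel_config(seed = NA), "seed")
})
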