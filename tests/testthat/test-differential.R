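# Moderated differential essentiality and the nomination gates.

make_two_group <- function(group_vals, ref_vals, gene = "G1") {
  v <- matrix(c(group_vals, ref_vals), ncol = 1,
              dimnames = list(sprintf("L%02d",
                                      seq_len(length(group_vals) +
                                                length(ref_vals))), gene))
  meta <- panel_metadata(rownames(v),
                         c(rep(TRUE, length(group_vals)),
                           rep(FALSE, length(ref_vals))))
  list(mat = score_matrix(v, "gene_effect"), meta = meta)
}

test_that("group difference matches the pooled-variance formulas", {
  tg <- make_two_group(c(-1.2, -1.0, -1.1, -0.9), c(0.0, -0.1, 0.1, -0.2, 0.2))
  rows <- group_difference(tg$mat, tg$meta)
  oracle <- oracle_pooled(c(-1.2, -1.0, -1.1, -0.9),
                          c(0.0, -0.1, 0.1, -0.2, 0.2))
  expect_equal(rows$lfc, oracle$lfc, tolerance = 1e-12)
  expect_equal(rows$s2, oracle$s2, tolerance = 1e-12)
  expect_equal(rows$df, oracle$df)
  # trivial arithmetic cases
  tg2 <- make_two_group(rep(0.9, 4), rep(0.1, 5))
  expect_equal(group_difference(tg2$mat, tg2$meta)$lfc, 0.8)
  tg3 <- make_two_group(c(1, 2, 3), c(1, 2, 3))
  expect_equal(group_difference(tg3$mat, tg3$meta)$lfc, 0)
})

test_that("missing values drop per gene and starved genes are flagged", {
  set.seed(3)
  v <- matrix(rnorm(8 * 3), 8, dimnames = list(sprintf("L%d", 1:8),
                                               c("A", "B", "C")))
  v[1:3, 2] <- NA         # only one usable group observation for B
  v[5, 3] <- NA
  meta <- panel_metadata(rownames(v), c(rep(TRUE, 4), rep(FALSE, 4)))
  rows <- group_difference(score_matrix(v, "gene_effect"), meta)
  expect_false(rows$usable[rows$gene == "B"])
  expect_true(rows$usable[rows$gene == "C"])
  expect_equal(rows$df[rows$gene == "C"], 5)  # 4 + 3 - 2
  g <- v[1:4, 3]; r <- v[5:8, 3]
  oracle <- oracle_pooled(g[!is.na(g)], r[!is.na(r)])
  expect_equal(rows$lfc[rows$gene == "C"], oracle$lfc, tolerance = 1e-12)
})

test_that("moderated t matches the independent formula oracle to 1e-10", {
  set.seed(101)
  n1 <- 4; n2 <- 30; n_genes <- 200
  v <- matrix(rnorm((n1 + n2) * n_genes, sd = rep(sqrt(rchisq(n_genes, 5) / 5),
                                                  each = n1 + n2)),
              n1 + n2, n_genes,
              dimnames = list(sprintf("L%02d", seq_len(n1 + n2)),
                              sprintf("G%03d", seq_len(n_genes))))
  meta <- panel_metadata(rownames(v), c(rep(TRUE, n1), rep(FALSE, n2)))
  rows <- empirical_bayes_moderation(
    group_difference(score_matrix(v, "gene_effect"), meta))
  oracle <- oracle_moderated(rows$lfc, rows$s2, rows$df, n1, n2)
  params <- attr(rows, "params")
  expect_equal(params$d0, oracle$d0, tolerance = 1e-8)
  expect_equal(params$s0_sq, oracle$s0_sq, tolerance = 1e-10)
  expect_equal(rows$t_mod, oracle$t, tolerance = 1e-10)
  expect_equal(rows$P, oracle$P, tolerance = 1e-10)
})

test_that("moderated t agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(202)
  n1 <- 4; n2 <- 40; n_genes <- 300
  v <- matrix(rnorm((n1 + n2) * n_genes,
                    sd = rep(sqrt(rchisq(n_genes, 4) / 4), each = n1 + n2)),
              n1 + n2, n_genes,
              dimnames = list(sprintf("L%02d", seq_len(n1 + n2)),
                              sprintf("G%03d", seq_len(n_genes))))
  meta <- panel_metadata(rownames(v), c(rep(TRUE, n1), rep(FALSE, n2)))
  rows <- empirical_bayes_moderation(
    group_difference(score_matrix(v, "gene_effect"), meta))
  design <- cbind(1, meta$group_flag)
  fit <- limma::eBayes(limma::lmFit(t(v), design))
  expect_equal(attr(rows, "params")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(rows, "params")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(rows$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(rows$P, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("degenerate dispersion collapses to d0 = Inf and fixed variance", {
  # identical s2 across genes: no excess dispersion, pure shrinkage
  rows <- data.frame(gene = sprintf("G%02d", 1:20),
                     lfc = c(0, seq(-1, 1, length.out = 19)),
                     s2 = rep(0.04, 20), df = rep(10, 20),
                     mean_group = 0, mean_ref = 0,
                     n_group = 4, n_ref = 8, usable = TRUE)
  out <- empirical_bayes_moderation(rows)
  params <- attr(out, "params")
  expect_identical(params$d0, Inf)
  s0_expected <- exp(mean(log(rows$s2)) - digamma(5) + log(5))
  expect_equal(params$s0_sq, s0_expected, tolerance = 1e-12)
  expect_equal(out$t_mod,
               rows$lfc / (sqrt(s0_expected) * sqrt(1 / 4 + 1 / 8)),
               tolerance = 1e-12)
  expect_equal(out$P[rows$lfc == 0], rep(1, sum(rows$lfc == 0)))
})

test_that("moderation limits: ordinary t at d0 -> 0, z-like at d0 -> Inf", {
  set.seed(9)
  rows <- data.frame(gene = sprintf("G%02d", 1:50),
                     lfc = rnorm(50), s2 = rchisq(50, 6) / 6, df = 6,
                     mean_group = 0, mean_ref = 0,
                     n_group = 4, n_ref = 4, usable = TRUE)
  sef <- sqrt(1 / 4 + 1 / 4)
  tiny <- empirical_bayes_moderation(rows, params = list(d0 = 1e-8, s0_sq = 1))
  expect_equal(tiny$t_mod, rows$lfc / (sef * sqrt(rows$s2)), tolerance = 1e-6)
  huge <- empirical_bayes_moderation(rows, params = list(d0 = 1e8, s0_sq = 0.7))
  expect_equal(huge$t_mod, rows$lfc / (sef * sqrt(0.7)), tolerance = 1e-6)
})

test_that("zero-variance genes get pure shrinkage, not infinite t", {
  rows <- data.frame(gene = c("A", "B"), lfc = c(0.5, 0.5),
                     s2 = c(0, 0.1), df = 10, mean_group = 0, mean_ref = 0,
                     n_group = 4, n_ref = 8, usable = TRUE)
  out <- empirical_bayes_moderation(rows, params = list(d0 = 4, s0_sq = 0.2))
  expect_equal(out$s2_post[1], 4 * 0.2 / (4 + 10), tolerance = 1e-12)
  expect_true(is.finite(out$t_mod[1]))
})

test_that("hyperparameter fitting refuses fewer than 10 usable genes", {
  expect_error(fit_variance_prior(rep(0.1, 5), rep(4, 5)), "fewer than 10")
})

test_that("trigamma inversion solves trigamma(y) = x across magnitudes", {
  y <- c(0.01, 0.5, 1, 7, 150, 3e4)
  expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-8)
})

test_that("BH adjustment matches step-up enumeration and p.adjust", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(bh_adjust(p), c(0.03, 0.03, 0.04), tolerance = 1e-12)
  set.seed(5)
  p2 <- runif(100)
  expect_equal(bh_adjust(p2), oracle_bh(p2), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  o <- sample(100)
  expect_equal(bh_adjust(p2[o]), oracle_bh(p2)[o], tolerance = 1e-12)
  # missing entries propagate
  expect_true(is.na(bh_adjust(c(0.1, NA, 0.3))[2]))
})

nomination_row <- function(gene, P_eff, lfc_eff, P_prob, lfc_prob,
                           mean_grp) {
  list(effect = data.frame(gene = gene, lfc = lfc_eff, P = P_eff),
       prob = data.frame(gene = gene, lfc = lfc_prob, P = P_prob,
                         mean_group = mean_grp))
}

test_that("nomination gates apply the published thresholds and directions", {
  genes <- c("hit_relaxed", "fails_p", "ref_selective", "hit_stringent")
  eff <- data.frame(gene = genes,
                    lfc = c(-0.45, -2.0, 0.6, -0.8),
                    P = c(0.015, 0.03, 0.001, 0.001))
  prob <- data.frame(gene = genes,
                     lfc = c(0.35, 0.9, -0.6, 0.7),
                     P = c(0.005, 0.001, 0.001, 0.001),
                     mean_group = c(0.8, 0.9, 0.3, 0.95))
  calls <- nominate_selective(eff, prob)
  expect_equal(calls$relaxed_status[calls$gene == "hit_relaxed"],
               "group_selective")
  expect_equal(calls$stringent_status[calls$gene == "hit_relaxed"],
               "not_selective")   # |lfc_prob| = 0.35 < 0.5
  expect_equal(calls$relaxed_status[calls$gene == "fails_p"],
               "not_selective")   # P_effect = 0.03 > 0.02
  expect_equal(calls$stringent_status[calls$gene == "fails_p"],
               "not_selective")
  expect_equal(calls$relaxed_status[calls$gene == "ref_selective"],
               "reference_selective")
  expect_equal(calls$stringent_status[calls$gene == "hit_stringent"],
               "group_selective")
})

test_that("genes present in only one table are excluded and reported", {
  eff <- data.frame(gene = c("A", "B"), lfc = c(1, 1), P = c(0.001, 0.001))
  prob <- data.frame(gene = c("A", "C"), lfc = c(0.8, 0.8),
                     P = c(0.001, 0.001), mean_group = c(0.9, 0.9))
  calls <- nominate_selective(eff, prob)
  expect_identical(sort(attr(calls, "excluded")), c("B", "C"))
  expect_identical(calls$gene, "A")
})

test_that("lowering a threshold never removes a nominated gene", {
  set.seed(77)
  n <- 200
  genes <- sprintf("G%03d", seq_len(n))
  eff <- data.frame(gene = genes, lfc = rnorm(n, 0, 0.6),
                    P = runif(n)^2)
  prob <- data.frame(gene = genes, lfc = rnorm(n, 0, 0.5),
                     P = runif(n)^2, mean_group = runif(n))
  base_cfg <- depsel_config()
  base <- nominate_selective(eff, prob, base_cfg)
  base_hits <- base$gene[base$relaxed_status != "not_selective"]
  looser <- depsel_config(relaxed_p = 0.05, relaxed_lfc_effect = 0.2,
                          relaxed_lfc_prob = 0.1)
  loose <- nominate_selective(eff, prob, looser)
  loose_hits <- loose$gene[loose$relaxed_status != "not_selective"]
  expect_true(all(base_hits %in% loose_hits))
})
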