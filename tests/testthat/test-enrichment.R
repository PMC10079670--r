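# Running-sum GSEA, hypergeometric, network enrichment, list-size AUC.

test_that("enrichment score endpoints behave as forced by the running sum", {
  rk <- ranked_list(c(A = 3, B = 2, C = 1, D = 0.5))
  expect_equal(preranked_enrichment_score(rk, "A")$ES, 1)
  expect_equal(preranked_enrichment_score(rk, "D")$ES, -1)
  # first k genes with equal metrics: full increment before any miss
  rk2 <- ranked_list(c(A = 2, B = 2, C = 2, D = 1, E = 0.5))
  res <- preranked_enrichment_score(rk2, c("A", "B", "C"))
  expect_equal(res$ES, 1)
  expect_identical(res$leading_edge, c("A", "B", "C"))
  expect_error(preranked_enrichment_score(rk, "ZZZ"), "empty intersection")
  expect_error(preranked_enrichment_score(rk, c("A", "B", "C", "D")),
               "entire ranking")
})

test_that("ES equals exhaustive enumeration for all subsets of small rankings", {
  for (n in c(5, 8, 10)) {
    set.seed(n)
    metric <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(metric) <- sprintf("g%02d", seq_len(n))
    rk <- ranked_list(metric)
    genes <- names(metric)
    for (mask in seq_len(2^n - 2)) {
      set <- genes[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))]
      if (length(set) == 0 || length(set) == n) next
      expect_equal(preranked_enrichment_score(rk, set)$ES,
                   oracle_es(metric, set), tolerance = 1e-12)
    }
  }
})

test_that("weight exponent reshapes hit increments as |metric|^w", {
  metric <- c(A = 4, B = 2, C = 1, D = 0.5, E = 0.25)
  rk <- ranked_list(metric)
  for (w in c(0, 1, 2)) {
    expect_equal(preranked_enrichment_score(rk, c("B", "D"), weight = w)$ES,
                 oracle_es(metric, c("B", "D"), weight = w),
                 tolerance = 1e-12)
  }
})

test_that("permutation GSEA is deterministic and floors extreme p-values", {
  set.seed(31)
  metric <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  metric[1:10] <- 100 + 1:10      # constructed top-10 set
  rk <- ranked_list(metric)
  sets <- list(top = names(sort(metric, decreasing = TRUE))[1:10],
               random = sprintf("g%04d", sample(1000, 25)))
  r1 <- gsea_permutation(rk, sets, n_perm = 1000, seed = 42)
  r2 <- gsea_permutation(rk, sets, n_perm = 1000, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$p_perm[r1$set_name == "top"], 1 / 1001)
  expect_gt(r1$NES[r1$set_name == "top"], 1)
  expect_true(all(r1$p_perm >= 1 / 1001))
  # results independent of set evaluation order
  r3 <- gsea_permutation(rk, rev(sets), n_perm = 1000, seed = 42)
  expect_equal(r3$ES[r3$set_name == "top"], r1$ES[r1$set_name == "top"])
  expect_equal(r3$p_perm[r3$set_name == "top"],
               r1$p_perm[r1$set_name == "top"])
})

test_that("observed ES agrees with the reference fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(61)
  metric <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  rk <- ranked_list(metric)
  sets <- list(s1 = sprintf("g%03d", sample(300, 20)),
               s2 = sprintf("g%03d", sample(300, 35)))
  mine <- vapply(sets, function(s) preranked_enrichment_score(rk, s)$ES, 0)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, metric, eps = 0, nPermSimple = 101))
  expect_equal(unname(mine[ref$pathway]), ref$ES, tolerance = 1e-10)
})

test_that("hypergeometric tail equals full enumeration", {
  # N = 10, K = 3, n = 3, k = 2 -> 22/120 by counting all C(10,3) lists
  res <- hypergeom_overlap_test(c("g1", "g2", "g4"), c("g1", "g2", "g3"),
                                sprintf("g%d", 1:10))
  expect_equal(res$k, 2)
  expect_equal(res$p, 22 / 120, tolerance = 1e-12)
  expect_equal(res$p, oracle_hypergeom(10, 3, 3, 2), tolerance = 1e-12)
  # list identical to set: minimal p for the configuration
  all_in <- hypergeom_overlap_test(c("g1", "g2", "g3"), c("g1", "g2", "g3"),
                                   sprintf("g%d", 1:10))
  expect_equal(all_in$p, 1 / choose(10, 3), tolerance = 1e-12)
  # zero overlap: tail includes everything
  none <- hypergeom_overlap_test("g9", c("g1", "g2"), sprintf("g%d", 1:10))
  expect_equal(none$p, 1)
  expect_error(hypergeom_overlap_test("a", "b", character(0)),
               "empty universe")
})

test_that("network enrichment counts cross edges and matches brute force", {
  # star: hub h with 10 leaves; set = hub, list = 3 leaves
  edges <- data.frame(from = "h", to = sprintf("l%02d", 1:10))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  lst <- c("l01", "l02", "l03")
  res <- network_list_enrichment(lst, "h", g, n_perm = 500, seed = 7)
  expect_equal(res$statistic, 3)
  # every leaf has degree 1, hub 10; a 3-leaf list always yields 3 cross
  # edges unless the hub itself is drawn -- enumerate the exact null
  expect_equal(res$p, 1.0, tolerance = 0.15)
  res2 <- network_list_enrichment(lst, "h", g, n_perm = 500, seed = 7)
  expect_identical(res, res2)
})

test_that("disjoint components give zero statistic and p near 1", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a1", "b1"), to = c("a2", "b2")), directed = FALSE)
  res <- network_list_enrichment(c("a1", "a2"), c("b1", "b2"), g,
                                 n_perm = 300, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("list-size AUC hits its formula endpoints and stays in [0, 1]", {
  expect_equal(listsize_auc(rep(1, 200))$auc, 0)
  expect_equal(listsize_auc(rep(0, 200))$auc, 1)
  expect_equal(listsize_auc(rep(1e-26, 200))$auc, 0.5, tolerance = 1e-12)
  # monotone non-increasing in any single p_adj(g)
  set.seed(13)
  p <- runif(200)
  base <- listsize_auc(p)$auc
  p2 <- p; p2[57] <- p2[57] / 10
  expect_gte(listsize_auc(p2)$auc, base)
  expect_true(base >= 0 && base <= 1)
  # clipping: p smaller than 10^-p_min contributes exactly p_min
  expect_equal(listsize_auc(rep(1e-60, 200))$auc, 1)
  expect_error(listsize_auc(c(rep(0.5, 199), NA)), "list size")
  expect_error(listsize_auc(rep(0.5, 100)), "expected 200")
})
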