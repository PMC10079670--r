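# Enrichment statistics: classic pre-ranked running-sum GSEA with a
# gene-label permutation null, hypergeometric over-representation, a
# degree-aware network list-enrichment test, and the list-size-normalized
# enrichment AUC used to rank gene sets robustly to top-list-size choice.

#' Construct a ranked gene list
#'
#' @param metric Named numeric vector: names are gene symbols, values the
#'   ranking metric (e.g. a differential statistic). Sorted descending on
#'   construction; duplicate genes or non-finite metrics are errors.
#' @return A named numeric vector of class `ranked_list`, sorted
#'   decreasing.
#' @export
ranked_list <- function(metric) {
  if (is.null(names(metric)) || any(!nzchar(names(metric)))) {
    stop("ranking metric must be named by gene")
  }
  if (anyDuplicated(names(metric))) {
    stop("duplicate gene in ranking: ",
         names(metric)[duplicated(names(metric))][1])
  }
  if (any(!is.finite(metric))) stop("ranking metric must be finite")
  out <- sort(metric, decreasing = TRUE)
  class(out) <- c("ranked_list", "numeric")
  out
}

# Running-sum extremum from sorted hit positions. `wts` are the hit
# increments already normalized to sum 1, aligned with `hits`; `n` is the
# ranking length. Returns the signed maximal deviation.
es_from_hits <- function(hits, wts, n) {
  k <- length(hits)
  miss_dec <- 1 / (n - k)
  cum_w <- cumsum(wts)
  at_hit <- cum_w - (hits - seq_len(k)) * miss_dec       # just after each hit
  before_hit <- c(0, cum_w[-k]) - (hits - seq_len(k)) * miss_dec
  top <- max(at_hit)
  bottom <- min(c(before_hit, 0))
  # tolerance so exact rational ties are not broken by float noise
  if (top >= -bottom - 1e-12) top else bottom
}

#' Pre-ranked enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum: walking down the
#' ranking, set members ("hits") increment the sum by
#' `|metric|^weight / sum(|metric|^weight over hits)` and non-members
#' decrement it by `1 / (N - n_hits)`. The enrichment score is the signed
#' maximal deviation from zero; the leading edge is the hits at or before
#' the extremum (at or after, for a negative score).
#'
#' If every hit has metric zero under `weight > 0`, hits fall back to
#' equal increments so the statistic remains defined.
#'
#' @param ranking A [ranked_list()].
#' @param set Character vector of gene symbols.
#' @param weight Weight exponent (default 1).
#' @return List with `ES`, `leading_edge` (character vector), `hits`
#'   (positions in the ranking).
#' @export
preranked_enrichment_score <- function(ranking, set, weight = 1) {
  genes <- names(ranking)
  n <- length(genes)
  hits <- sort(which(genes %in% set))
  if (length(hits) == 0) stop("gene set has empty intersection with ranking")
  if (length(hits) == n) stop("gene set covers the entire ranking")
  w <- abs(as.numeric(ranking)[hits])^weight
  if (sum(w) == 0) w <- rep(1, length(hits))
  wts <- w / sum(w)
  k <- length(hits)
  miss_dec <- 1 / (n - k)
  cum_w <- cumsum(wts)
  at_hit <- cum_w - (hits - seq_len(k)) * miss_dec
  before_hit <- c(0, cum_w[-k]) - (hits - seq_len(k)) * miss_dec
  top_i <- which.max(at_hit)
  top <- at_hit[top_i]
  bot_i <- which.min(before_hit)
  bottom <- min(before_hit[bot_i], 0)
  if (top >= -bottom - 1e-12) {
    es <- top
    leading <- genes[hits[seq_len(top_i)]]
  } else {
    es <- bottom
    leading <- genes[hits[hits >= hits[bot_i]]]
  }
  list(ES = es, leading_edge = leading, hits = hits)
}

#' Permutation-based pre-ranked GSEA over a gene-set collection
#'
#' For each set, computes the observed enrichment score, then a null of
#' `n_perm` scores from random same-size gene sets drawn from the ranking
#' (gene-label permutation). The normalized score divides the observed ES
#' by the mean absolute null ES of matching sign (missing when fewer than
#' 3 sign-matched null values exist); the permutation p-value is
#' `(1 + #{same-sign null at least as extreme}) / (1 + n_perm)` and is
#' adjusted across sets by Benjamini-Hochberg.
#'
#' @param ranking A [ranked_list()].
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; identical seeds give identical results.
#' @param weight Weight exponent for the running sum.
#' @return Data frame with one row per set: `set_name`, `size` (genes in
#'   the ranking), `ES`, `NES`, `p_perm`, `p_adj`, `leading_edge`
#'   (comma-separated), `n_perm`, `seed`.
#' @export
gsea_permutation <- function(ranking, sets, n_perm = 1000, seed = 1L,
                             weight = 1) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (n_perm < 100) stop("n_perm must be >= 100")
  genes <- names(ranking)
  n <- length(genes)
  absw <- abs(as.numeric(ranking))^weight
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    set_genes <- intersect(sets[[i]], genes)
    k <- length(set_genes)
    if (k == 0 || k == n) {
      rows[[i]] <- data.frame(set_name = names(sets)[i], size = k,
                              ES = NA_real_, NES = NA_real_,
                              p_perm = NA_real_, leading_edge = "",
                              stringsAsFactors = FALSE)
      next
    }
    if (k > n / 2) {
      warning("set '", names(sets)[i],
              "' covers more than half the ranking; null poorly calibrated")
    }
    obs <- preranked_enrichment_score(ranking, set_genes, weight)
    # dedicated substream per set so results do not depend on set order
    set.seed(substream_seed(seed, paste0("gsea:", names(sets)[i])))
    null_es <- vapply(seq_len(n_perm), function(p) {
      hits <- sort(sample.int(n, k))
      w <- absw[hits]
      if (sum(w) == 0) w <- rep(1, k)
      es_from_hits(hits, w / sum(w), n)
    }, 0)
    same_sign <- if (obs$ES >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    # two-sided on magnitude over all permutations: exactly uniform under
    # the null by exchangeability of |ES|, with the 1/(n_perm + 1) floor
    p_perm <- (1 + sum(abs(null_es) >= abs(obs$ES))) / (1 + n_perm)
    nes <- if (length(same_sign) >= 3) {
      obs$ES / mean(abs(same_sign))
    } else NA_real_
    rows[[i]] <- data.frame(set_name = names(sets)[i], size = k,
                            ES = obs$ES, NES = nes, p_perm = p_perm,
                            leading_edge = paste(obs$leading_edge,
                                                 collapse = ","),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_perm)
  out$n_perm <- n_perm
  out$seed <- as.integer(seed)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' gene list and a gene set drawn from a finite universe.
#'
#' @param list_genes,set_genes Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes (non-empty).
#' @return List with `k` (overlap) and `p` (upper-tail probability of
#'   overlap >= k).
#' @export
hypergeom_overlap_test <- function(list_genes, set_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  list_genes <- unique(list_genes); set_genes <- unique(set_genes)
  if (!all(list_genes %in% universe) || !all(set_genes %in% universe)) {
    stop("list and set must be subsets of the universe")
  }
  k <- length(intersect(list_genes, set_genes))
  p <- stats::phyper(k - 1, length(set_genes),
                     length(universe) - length(set_genes),
                     length(list_genes), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Network list enrichment with a degree-stratified null
#'
#' Tests whether a gene list is unusually connected to a gene set in an
#' interaction network. The statistic counts graph edges with one endpoint
#' in the list and the other in the set (each edge once). The null draws
#' `n_perm` random lists of equal size stratified by degree decile, so
#' hub-heavy lists are compared against hub-heavy random lists.
#'
#' @param list_genes,set_genes Character vectors of gene symbols; genes
#'   absent from the graph are dropped (count reported via message).
#' @param graph An `igraph` undirected graph with vertex `name`s.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @return List with `statistic` (observed cross-edge count), `p`,
#'   `n_list` (list size after filtering), `n_perm`, `seed`.
#' @export
network_list_enrichment <- function(list_genes, set_genes, graph,
                                    n_perm = 1000, seed = 1L) {
  nodes <- igraph::V(graph)$name
  dropped <- sum(!list_genes %in% nodes) + sum(!set_genes %in% nodes)
  if (dropped > 0) {
    message(dropped, " gene(s) absent from the graph were dropped")
  }
  list_genes <- unique(intersect(list_genes, nodes))
  set_genes <- unique(intersect(set_genes, nodes))
  if (length(list_genes) == 0) stop("gene list empty after node filtering")
  em <- igraph::as_edgelist(graph, names = TRUE)
  cross_edges <- function(lst) {
    a_in_l <- em[, 1] %in% lst; b_in_l <- em[, 2] %in% lst
    a_in_s <- em[, 1] %in% set_genes; b_in_s <- em[, 2] %in% set_genes
    sum((a_in_l & b_in_s) | (b_in_l & a_in_s))
  }
  observed <- cross_edges(list_genes)
  deg <- igraph::degree(graph)
  # degree strata over all graph nodes (at most 10 bins, equal-degree
  # nodes never split); null lists match the observed list's composition
  ud <- sort(unique(deg))
  decile <- if (length(ud) <= 10) {
    match(deg, ud)
  } else {
    qs <- unique(stats::quantile(deg, probs = seq(0, 1, by = 0.1),
                                 type = 1))
    findInterval(deg, qs, rightmost.closed = TRUE)
  }
  names(decile) <- nodes
  list_strata <- table(decile[list_genes])
  set.seed(substream_seed(seed, "network_enrichment"))
  null_stat <- vapply(seq_len(n_perm), function(p) {
    draw <- unlist(lapply(names(list_strata), function(d) {
      pool <- nodes[decile == as.integer(d)]
      pool[sample.int(length(pool), list_strata[[d]])]
    }), use.names = FALSE)
    cross_edges(draw)
  }, 0)
  p <- (1 + sum(null_stat >= observed)) / (1 + n_perm)
  list(statistic = observed, p = p, n_list = length(list_genes),
       n_perm = n_perm, seed = as.integer(seed))
}

#' List-size-normalized enrichment AUC
#'
#' Summarizes a curve of adjusted enrichment p-values over top-list sizes
#' `g = 1..G` into one number: `-log10(p_adj(g))` is clipped to
#' `[0, p_min]` (an exact zero maps to `p_min`, the saturation value of
#' `-log10` at floating-point accuracy), summed over the integer grid and
#' scaled by `1 / (G * p_min)`, giving a value in \[0, 1\] by which gene
#' sets can be ranked robustly to the choice of list size.
#'
#' @param p_adj_by_g Numeric vector of adjusted p-values, position `g`
#'   holding the value for the top-`g` list; length `G`, no gaps.
#' @param p_min Saturation constant (default 52).
#' @param G Number of list sizes (default 200).
#' @param set_name Optional label.
#' @return An object of class `auc_curve`: list with `set_name`, `g`,
#'   `p_adj`, `neglog` (clipped curve), `p_min`, `auc`.
#' @export
listsize_auc <- function(p_adj_by_g, p_min = 52, G = 200, set_name = "") {
  if (length(p_adj_by_g) != G) {
    stop("expected ", G, " values (one per list size), got ",
         length(p_adj_by_g))
  }
  gaps <- which(is.na(p_adj_by_g))
  if (length(gaps) > 0) {
    stop("missing p_adj at list size(s): ",
         paste(utils::head(gaps, 10), collapse = ", "))
  }
  if (any(p_adj_by_g < 0 | p_adj_by_g > 1)) {
    stop("adjusted p-values must lie in [0, 1]")
  }
  neglog <- ifelse(p_adj_by_g == 0, p_min,
                   pmin(pmax(-log10(p_adj_by_g), 0), p_min))
  auc <- sum(neglog) / (G * p_min)
  structure(list(set_name = set_name, g = seq_len(G), p_adj = p_adj_by_g,
                 neglog = neglog, p_min = p_min, auc = auc),
            class = "auc_curve")
}

#' @export
print.auc_curve <- function(x, ...) {
  cat(sprintf("auc_curve '%s': G = %d, p_min = %g, AUC = %.4f\n",
              x$set_name, length(x$g), x$p_min, x$auc))
  invisible(x)
}
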