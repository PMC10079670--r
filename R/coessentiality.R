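# Co-essentiality: genes with correlated dependency-probability profiles
# across the panel tend to act in the same pathway, so a thresholded
# correlation graph groups candidate dependencies into functional modules.

#' Pairwise-complete correlations between dependency profiles
#'
#' Pearson correlation between the score profiles of every pair of the
#' requested genes across all cell lines, using pairwise-complete
#' observations. A pair with fewer than `min_pair_obs` shared complete
#' observations, or involving a constant profile, gets a missing
#' correlation (with a warning naming constant genes).
#'
#' @param mat A [score_matrix()] (typically dependency probabilities).
#' @param genes Genes to correlate; must be columns of `mat`.
#' @param min_pair_obs Minimum shared complete observations (default 3).
#' @return List with `r` (symmetric correlation matrix, unit diagonal)
#'   and `n_obs` (pairwise-complete counts).
#' @export
profile_correlations <- function(mat, genes, min_pair_obs = 3) {
  stopifnot(inherits(mat, "score_matrix"))
  missing_genes <- setdiff(genes, colnames(mat$values))
  if (length(missing_genes) > 0) {
    stop("genes absent from matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  v <- mat$values[, genes, drop = FALSE]
  obs <- !is.na(v)
  n_obs <- crossprod(obs)
  suppressWarnings(
    r <- stats::cor(v, use = "pairwise.complete.obs", method = "pearson"))
  const <- vapply(seq_along(genes), function(j) {
    x <- v[obs[, j], j]
    length(x) > 0 && stats::sd(x) == 0
  }, TRUE)
  if (any(const)) {
    warning("constant profile(s), correlations set missing: ",
            paste(genes[const], collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  r[n_obs < min_pair_obs] <- NA_real_
  diag(r) <- 1
  list(r = r, n_obs = n_obs)
}

#' Build a thresholded co-essentiality network
#'
#' Connects gene pairs whose profile correlation is at least `threshold`
#' (inclusive), annotates edges with the correlation as weight, nodes with
#' an optional score (e.g. median group dependency probability), and
#' reports connected components and singletons separately.
#'
#' @param correlations Output of [profile_correlations()] (or a symmetric
#'   correlation matrix).
#' @param threshold Edge threshold in (0, 1\], inclusive; default 0.18.
#' @param node_scores Optional named numeric vector of node annotations.
#' @return List of class `network_graph`: `graph` (igraph), `threshold`,
#'   `components` (list of gene vectors, singletons excluded),
#'   `singletons` (character vector), `edges` (data frame `gene_a`,
#'   `gene_b`, `weight`).
#' @export
build_network <- function(correlations, threshold = 0.18,
                          node_scores = NULL) {
  r <- if (is.list(correlations)) correlations$r else correlations
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  genes <- colnames(r)
  idx <- which(upper.tri(r) & !is.na(r) & r >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = r[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  if (!is.null(node_scores)) {
    igraph::V(g)$score <- as.numeric(node_scores[genes])
  }
  comp <- igraph::components(g)
  members <- split(genes, comp$membership)
  singletons <- sort(unlist(members[lengths(members) == 1], use.names = FALSE))
  components <- unname(members[lengths(members) > 1])
  structure(list(graph = g, threshold = threshold, components = components,
                 singletons = singletons, edges = edges),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf(
    "network_graph: %d nodes, %d edges (threshold %g), %d components, %d singletons\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold,
    length(x$components), length(x$singletons)))
  invisible(x)
}

#' Confidence-filtered interaction subnetwork
#'
#' Induces the subgraph of an interaction table on a gene list, keeping
#' edges with confidence at least `min_conf` (inclusive). Genes from the
#' list with no surviving edge are retained as isolated nodes; edges
#' touching genes outside the list are dropped and counted.
#'
#' @param table An [interaction_table()].
#' @param min_conf Minimum confidence, inclusive (default 0.4).
#' @param genes Gene list defining the node universe.
#' @return A `network_graph` (see [build_network()]); the number of edges
#'   dropped for unknown genes is in `attr(, "dropped_unknown")`.
#' @export
filter_interaction_edges <- function(table, min_conf = 0.4, genes) {
  stopifnot(inherits(table, "interaction_table"))
  known <- table$gene_a %in% genes & table$gene_b %in% genes
  dropped <- sum(!known)
  if (dropped > 0) {
    message(dropped, " edge(s) touching genes outside the list were dropped")
  }
  keep <- known & table$confidence >= min_conf
  edges <- data.frame(gene_a = table$gene_a[keep],
                      gene_b = table$gene_b[keep],
                      weight = table$confidence[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  members <- split(genes, comp$membership)
  singletons <- sort(unlist(members[lengths(members) == 1], use.names = FALSE))
  out <- structure(list(graph = g, threshold = min_conf,
                        components = unname(members[lengths(members) > 1]),
                        singletons = singletons, edges = edges),
                   class = "network_graph")
  attr(out, "dropped_unknown") <- dropped
  out
}

#' Write a network as an edge-list TSV
#' @param net A `network_graph`.
#' @param path Output path. Singletons are appended as rows with empty
#'   `gene_b`.
#' @export
write_network <- function(net, path) {
  edges <- net$edges
  if (length(net$singletons) > 0) {
    edges <- rbind(edges, data.frame(gene_a = net$singletons, gene_b = "",
                                     weight = NA_real_))
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
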