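# Copy-number neighborhood scan: copy-number correlates of a dependency
# often reflect a whole co-amplified/co-deleted chromosomal segment rather
# than one causal gene. The scan asks whether the correlate list is
# enriched for physical neighbors of a nominated anchor gene, over a grid
# of genomic window sizes, and picks the window with maximal enrichment.

#' Genes within a genomic window around an anchor
#'
#' Returns the genes on the anchor's chromosome whose midpoints fall in
#' the centered span of total width `w` around the anchor midpoint,
#' i.e. `[midpoint - w/2, midpoint + w/2]` (bounds inclusive by default).
#'
#' @param anchor Anchor gene symbol (must be present in `coords`).
#' @param coords A [gene_coords()] table.
#' @param w Window span in bp (total width, > 0).
#' @param include_anchor Include the anchor itself (default TRUE).
#' @param inclusive Treat the window bounds as inclusive (default TRUE).
#' @return Character vector of gene symbols.
#' @export
genes_in_window <- function(anchor, coords, w, include_anchor = TRUE,
                            inclusive = TRUE) {
  stopifnot(w > 0)
  i <- match(anchor, coords$gene_symbol)
  if (is.na(i)) stop("anchor gene '", anchor, "' absent from coordinates")
  mid <- coords$midpoint[i]
  chrom <- coords$chromosome[i]
  same <- coords$chromosome == chrom
  d <- abs(coords$midpoint - mid)
  inside <- if (inclusive) d <= w / 2 else d < w / 2
  hits <- coords$gene_symbol[same & inside]
  if (!include_anchor) hits <- setdiff(hits, anchor)
  hits
}

#' Window-size-optimized neighborhood enrichment scan
#'
#' For each window span on the grid, forms the member gene set around the
#' anchor via [genes_in_window()] and computes its pre-ranked permutation
#' enrichment against the copy-number correlate ranking (correlation `r`,
#' ranked decreasing). The selected window has the smallest permutation
#' p-value; ties are broken by larger absolute enrichment score, then by
#' smaller span. Windows whose member set does not intersect the ranking
#' are skipped with a warning; if all are skipped, the scan errors.
#'
#' @param anchor Anchor gene symbol.
#' @param coords A [gene_coords()] table.
#' @param ranked_correlates Either a [ranked_list()] (metric = correlation
#'   with the dependency) or the data frame returned by
#'   [dependency_feature_correlations()] on copy-number features.
#' @param config A [depsel_config()] (supplies the window grid, inclusion
#'   rules, permutation count, weight and seed).
#' @return An object of class `window_scan`: data frame `windows` with
#'   per-window `w`, `n_members`, `n_in_ranking`, `ES`, `p_perm`, the
#'   selected span `selected_w`, its member set `selected_members`, plus
#'   `anchor` and `seed`.
#' @export
window_enrichment_scan <- function(anchor, coords, ranked_correlates,
                                   config = depsel_config()) {
  if (is.data.frame(ranked_correlates)) {
    keep <- !is.na(ranked_correlates$r)
    metric <- ranked_correlates$r[keep]
    names(metric) <- ranked_correlates$feature_id[keep]
    ranking <- ranked_list(metric)
  } else {
    ranking <- ranked_correlates
  }
  if (length(ranking) < 100) {
    stop("ranked correlate list must cover >= 100 genes")
  }
  grid <- sort(config$window_grid)
  rows <- vector("list", length(grid))
  members_by_w <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    w <- grid[i]
    members <- genes_in_window(anchor, coords, w,
                               include_anchor = config$include_anchor,
                               inclusive = config$inclusive_bounds)
    members_by_w[[i]] <- members
    in_rank <- intersect(members, names(ranking))
    if (length(in_rank) == 0 || length(in_rank) == length(ranking)) {
      warning("window ", format(w, scientific = FALSE),
              " bp skipped (member set does not form a proper subset of the ranking)")
      rows[[i]] <- data.frame(w = w, n_members = length(members),
                              n_in_ranking = length(in_rank),
                              ES = NA_real_, p_perm = NA_real_)
      next
    }
    res <- gsea_permutation(ranking,
                            stats::setNames(list(in_rank), "window"),
                            n_perm = config$n_perm,
                            seed = substream_seed(config$seed,
                                                  paste0("cn_window:", w)),
                            weight = config$gsea_weight)
    rows[[i]] <- data.frame(w = w, n_members = length(members),
                            n_in_ranking = length(in_rank),
                            ES = res$ES, p_perm = res$p_perm)
  }
  windows <- do.call(rbind, rows)
  usable <- which(!is.na(windows$p_perm))
  if (length(usable) == 0) stop("every window was skipped; nothing to select")
  # smallest p, then larger |ES|, then smaller span
  ord <- usable[order(windows$p_perm[usable], -abs(windows$ES[usable]),
                      windows$w[usable])]
  sel <- ord[1]
  structure(list(anchor = anchor, windows = windows,
                 selected_w = windows$w[sel],
                 selected_members = members_by_w[[sel]],
                 seed = config$seed),
            class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "window_scan anchor %s: %d windows, selected %s bp (%d member genes)\n",
    x$anchor, nrow(x$windows), format(x$selected_w, scientific = FALSE),
    length(x$selected_members)))
  invisible(x)
}
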