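# ZMAD signature scoring: per-gene modified z-scores centered on the
# panel median with an absolute-deviation scale, averaged over a gene
# signature per cell line, then ranked across lineages. Robust centering
# keeps a handful of extreme lines from defining the scale.

#' Modified z-score (ZMAD) transform of an expression matrix
#'
#' Per gene (column): center = median across cell lines; scale = mean
#' absolute deviation about the median (default mode) or the median
#' absolute deviation; `ZMAD = (x - center) / scale`. Genes with zero
#' scale carry no ranking information and are dropped with a warning;
#' they are listed in the exclusion log.
#'
#' Operates on raw TPM by default. Pass `allow_log = TRUE` to transform a
#' log-scale expression matrix deliberately.
#'
#' @param expr A [feature_matrix()] of kind `expression_tpm` (or
#'   `expression_log2tpm` with `allow_log = TRUE`).
#' @param scale_mode `"mean_abs_dev_from_median"` (default) or
#'   `"median_abs_dev"` (unscaled, no consistency constant).
#' @param allow_log Permit log-scale input.
#' @return Object of class `zmad_matrix`: list with `values` (cell lines
#'   x retained genes), `center`, `scale` (named per gene), `scale_mode`,
#'   `excluded` (zero-scale genes).
#' @export
zmad_transform <- function(expr,
                           scale_mode = c("mean_abs_dev_from_median",
                                          "median_abs_dev"),
                           allow_log = FALSE) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(inherits(expr, "feature_matrix"))
  if (expr$kind != "expression_tpm" &&
      !(expr$kind == "expression_log2tpm" && allow_log)) {
    stop("zmad_transform expects expression_tpm input ",
         "(set allow_log = TRUE for log-scale matrices)")
  }
  v <- expr$values
  if (nrow(v) < 3) stop("need >= 3 cell lines")
  center <- apply(v, 2, stats::median, na.rm = TRUE)
  dev <- abs(sweep(v, 2, center, "-"))
  scl <- if (scale_mode == "mean_abs_dev_from_median") {
    colMeans(dev, na.rm = TRUE)
  } else {
    apply(dev, 2, stats::median, na.rm = TRUE)
  }
  zero <- !is.na(scl) & scl == 0
  if (any(zero)) {
    warning(sum(zero), " zero-scale gene(s) dropped: ",
            paste(utils::head(colnames(v)[zero], 5), collapse = ", "))
  }
  keep <- !zero & !is.na(scl)
  z <- sweep(sweep(v[, keep, drop = FALSE], 2, center[keep], "-"),
             2, scl[keep], "/")
  structure(list(values = z, center = center[keep], scale = scl[keep],
                 scale_mode = scale_mode,
                 excluded = colnames(v)[zero]),
            class = "zmad_matrix")
}

#' @export
print.zmad_matrix <- function(x, ...) {
  cat(sprintf("zmad_matrix [%s]: %d cell lines x %d genes (%d excluded)\n",
              x$scale_mode, nrow(x$values), ncol(x$values),
              length(x$excluded)))
  invisible(x)
}

#' Per-cell-line signature score
#'
#' Mean ZMAD over the signature genes present in the matrix; the number
#' of genes actually used is reported per cell line (cell lines missing
#' all signature genes get a missing score).
#'
#' @param zmad A `zmad_matrix` from [zmad_transform()].
#' @param signature Character vector of gene symbols, or a
#'   [gene_set_collection()] with a single set.
#' @param name Signature label.
#' @return Data frame of class `signature_scores`: `cell_line_id`,
#'   `score`, `n_genes_used`, with the signature name in
#'   `attr(, "signature")` and absent genes in `attr(, "missing_genes")`.
#' @export
signature_score <- function(zmad, signature, name = "signature") {
  if (inherits(signature, "gene_set_collection")) {
    if (length(signature$sets) != 1) {
      stop("pass a single-set collection or a gene vector")
    }
    name <- names(signature$sets)
    signature <- signature$sets[[1]]
  }
  present <- intersect(signature, colnames(zmad$values))
  absent <- setdiff(signature, colnames(zmad$values))
  if (length(present) == 0) {
    stop("no signature gene present in the matrix; missing: ",
         paste(utils::head(absent, 10), collapse = ", "))
  }
  sub <- zmad$values[, present, drop = FALSE]
  out <- data.frame(cell_line_id = rownames(sub),
                    score = rowMeans(sub, na.rm = TRUE),
                    n_genes_used = rowSums(!is.na(sub)),
                    stringsAsFactors = FALSE)
  out$score[out$n_genes_used == 0] <- NA_real_
  rownames(out) <- NULL
  attr(out, "signature") <- name
  attr(out, "missing_genes") <- absent
  class(out) <- c("signature_scores", "data.frame")
  out
}

#' Lineage-level ranking of signature scores
#'
#' Groups cell lines by lineage annotation, drops lines without a
#' lineage, lineages below `min_lines` members, and any label on the
#' exclusion list, then ranks lineages by median score (1 = highest; ties
#' broken by lineage name). The disease group (`group_flag`) is ranked as
#' its own category against the retained reference lineages.
#'
#' @param scores A `signature_scores` data frame.
#' @param meta A [panel_metadata()] with lineage labels.
#' @param min_lines Minimum lines per retained lineage (default 2).
#' @param exclude Lineage labels always dropped (default `"Engineered"`).
#' @param group_label Label under which the disease group is ranked.
#' @return Object of class `lineage_ranking`: data frame `lineages`
#'   (`lineage`, `n_lines`, `median_score`, `rank`), `group_rank`,
#'   `n_lineages` (reference lineages retained), `exclusion_log`.
#' @export
lineage_ranking <- function(scores, meta, min_lines = 2,
                            exclude = "Engineered",
                            group_label = "disease_group") {
  m <- meta[match(scores$cell_line_id, meta$cell_line_id), ]
  if (!any(m$group_flag, na.rm = TRUE)) {
    stop("query group absent from the scored cell lines")
  }
  lineage <- ifelse(m$group_flag, group_label, m$lineage)
  excl <- list()
  keep <- rep(TRUE, nrow(scores))
  no_annot <- !m$group_flag & (is.na(lineage) | !nzchar(lineage))
  if (any(no_annot)) {
    excl$no_annotation <- scores$cell_line_id[no_annot]
    keep <- keep & !no_annot
  }
  on_list <- !m$group_flag & lineage %in% exclude
  if (any(on_list)) {
    excl$excluded_label <- unique(lineage[on_list])
    keep <- keep & !on_list
  }
  lin <- lineage[keep]
  sc <- scores$score[keep]
  counts <- table(lin)
  small <- setdiff(names(counts)[counts < min_lines], group_label)
  if (length(small) > 0) {
    excl$below_min_lines <- small
    ok <- !(lin %in% small)
    lin <- lin[ok]; sc <- sc[ok]
  }
  med <- tapply(sc, lin, stats::median, na.rm = TRUE)
  tab <- data.frame(lineage = names(med),
                    n_lines = as.integer(table(lin)[names(med)]),
                    median_score = as.numeric(med),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$median_score, tab$lineage), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(lineages = tab,
                 group_rank = tab$rank[tab$lineage == group_label],
                 n_lineages = sum(tab$lineage != group_label),
                 exclusion_log = excl),
            class = "lineage_ranking")
}

#' @export
print.lineage_ranking <- function(x, ...) {
  cat(sprintf(
    "lineage_ranking: group rank %d of %d reference lineages (+ group)\n",
    x$group_rank, x$n_lineages))
  invisible(x)
}
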