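# End-to-end orchestration: simulate (or load) a panel, run differential
# essentiality on both score measures, nominate selective genes, build the
# co-essentiality network, scan biomarker correlates for planted
# dependencies, run the copy-number window scan, and score the interferon
# signature — writing standard-format outputs and a JSON run report.

#' Run the full selective-dependency pipeline
#'
#' Stages run in the order of the analysis: differential essentiality
#' (gene effect + dependency probability) with empirical-Bayes
#' moderation, selectivity nomination under both gates, co-essentiality
#' network over the nominated genes, copy-number biomarker scan and
#' window-optimized neighborhood enrichment for the panel's planted (or
#' user-named) anchors, ZMAD interferon-signature scoring with lineage
#' ranking, and truth-based recovery metrics when a truth table is
#' available. Stages whose inputs are absent are skipped and recorded in
#' the report; any hard error aborts with the stage name.
#'
#' @param inputs `"simulate"` (default) to generate a synthetic panel, or
#'   a list with elements `gene_effect`, `dependency_probability`
#'   ([score_matrix()]s), `meta` ([panel_metadata()]), and optionally
#'   `expression`, `copy_number`, `mutations` (feature matrices),
#'   `coords` ([gene_coords()]), `truth`.
#' @param config A [depsel_config()].
#' @param panel_config A [synthetic_panel_config()] used when
#'   `inputs = "simulate"`; its seed is overridden by `config$seed`.
#' @param out_dir Optional directory for TSV/JSON outputs; nothing is
#'   written when `NULL`.
#' @return A list of class `depsel_run`: `config`, `nominations` (data
#'   frame), `gene_lists` (per gate), `network`, `biomarker` (per planted
#'   dependency), `window_scan`, `isg` (scores + lineage ranking),
#'   `recovery` (when truth available), `skipped` (character vector),
#'   `report` (plain-list mirror written as JSON).
#' @export
run_pipeline <- function(inputs = "simulate", config = depsel_config(),
                         panel_config = NULL, out_dir = NULL) {
  skipped <- character()
  if (identical(inputs, "simulate")) {
    pc <- if (is.null(panel_config)) {
      synthetic_panel_config(seed = config$seed)
    } else {
      panel_config$seed <- config$seed
      panel_config
    }
    panel <- simulate_panel(pc)
  } else {
    panel <- inputs
  }
  need <- c("gene_effect", "dependency_probability", "meta")
  miss <- need[!need %in% names(panel)]
  if (length(miss) > 0) {
    stop("pipeline stage 'differential': missing required input(s): ",
         paste(miss, collapse = ", "))
  }

  diff_effect <- differential_essentiality(panel$gene_effect, panel$meta)
  diff_prob <- differential_essentiality(panel$dependency_probability,
                                         panel$meta)
  nominations <- nominate_selective(diff_effect, diff_prob, config)
  gene_lists <- list(
    stringent = nominations$gene[nominations$stringent_status ==
                                   "group_selective"],
    relaxed = nominations$gene[nominations$relaxed_status ==
                                 "group_selective"])

  network <- NULL
  if (length(gene_lists$relaxed) >= 2) {
    cors <- profile_correlations(panel$dependency_probability,
                                 gene_lists$relaxed,
                                 min_pair_obs = config$min_pair_obs)
    node_scores <- apply(
      panel$dependency_probability$values[panel$meta$group_flag,
                                          gene_lists$relaxed, drop = FALSE],
      2, stats::median, na.rm = TRUE)
    network <- build_network(cors, threshold = config$coess_threshold,
                             node_scores = node_scores)
  } else {
    skipped <- c(skipped, "coessentiality")
  }

  biomarker <- list()
  window_scan <- NULL
  truth <- panel$truth
  if (!is.null(panel$copy_number) && !is.null(truth)) {
    for (i in seq_len(nrow(truth$biomarkers))) {
      dep <- truth$biomarkers$dependency_gene[i]
      kind <- truth$biomarkers$feature_kind[i]
      feats <- switch(kind, copy_number = panel$copy_number,
                      mutation_binary = panel$mutations,
                      expression_log2tpm = panel$expression)
      if (is.null(feats)) next
      profile <- panel$gene_effect$values[, dep]
      # rank in the direction of the planted association so the truth
      # feature is expected near the top of its list
      biomarker[[dep]] <- dependency_feature_correlations(
        stats::setNames(profile, rownames(panel$gene_effect$values)),
        feats, min_overlap = config$min_pair_obs,
        decreasing = (truth$biomarkers$direction[i] == "positive"))
    }
    if (!is.null(panel$coords)) {
      dep <- truth$window$dependency_gene
      window_scan <- window_enrichment_scan(
        truth$window$anchor, panel$coords, biomarker[[dep]], config)
    } else {
      skipped <- c(skipped, "cn_window")
    }
  } else {
    skipped <- c(skipped, "biomarker", "cn_window")
  }

  isg <- NULL
  if (!is.null(panel$expression)) {
    zm <- zmad_transform(panel$expression,
                         scale_mode = config$zmad_scale_mode)
    scores <- signature_score(zm, isg_core_signature())
    ranking <- lineage_ranking(scores, panel$meta,
                               min_lines = config$lineage_min_lines,
                               exclude = config$lineage_exclude)
    isg <- list(scores = scores, ranking = ranking)
  } else {
    skipped <- c(skipped, "signatures")
  }

  recovery <- if (!is.null(truth)) {
    list(relaxed = evaluate_recovery(nominations, truth$genes, "relaxed"),
         stringent = evaluate_recovery(nominations, truth$genes,
                                       "stringent"))
  } else NULL

  report <- list(
    config = unclass(config),
    seed = config$seed,
    n_lines = nrow(panel$gene_effect$values),
    n_genes = ncol(panel$gene_effect$values),
    universe_hash = unname(substr(digest_genes(
      colnames(panel$gene_effect$values)), 1, 16)),
    nominated = lapply(gene_lists, sort),
    n_nominated = lapply(gene_lists, length),
    skipped = skipped,
    recovery = recovery,
    selected_window_bp = if (!is.null(window_scan)) window_scan$selected_w,
    isg_group_rank = if (!is.null(isg)) isg$ranking$group_rank,
    n_reference_lineages = if (!is.null(isg)) isg$ranking$n_lineages)

  out <- structure(list(config = config, nominations = nominations,
                        gene_lists = gene_lists, network = network,
                        biomarker = biomarker, window_scan = window_scan,
                        isg = isg, recovery = recovery, skipped = skipped,
                        report = report, panel = panel),
                   class = "depsel_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# Order-stable content hash of the gene universe (djb2), so the report
# can show when stage-skipping altered downstream inputs.
digest_genes <- function(genes) {
  h <- 5381
  for (ch in utf8ToInt(paste(sort(genes), collapse = ","))) {
    h <- (h * 33 + ch) %% 2^31
  }
  format(h, scientific = FALSE)
}

#' @export
print.depsel_run <- function(x, ...) {
  cat(sprintf(
    "depsel_run: %d stringent / %d relaxed group-selective nominations%s\n",
    length(x$gene_lists$stringent), length(x$gene_lists$relaxed),
    if (length(x$skipped) > 0) {
      paste0(" (skipped: ", paste(x$skipped, collapse = ", "), ")")
    } else ""))
  invisible(x)
}

#' Write pipeline outputs and the JSON run report
#' @param run A `depsel_run`.
#' @param dir Output directory.
#' @return Path of the JSON report.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$nominations, file.path(dir, "nominations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$network)) {
    write_network(run$network, file.path(dir, "coessentiality_edges.tsv"))
  }
  for (dep in names(run$biomarker)) {
    utils::write.table(run$biomarker[[dep]],
                       file.path(dir, paste0("biomarker_", dep, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$window_scan)) {
    utils::write.table(run$window_scan$windows,
                       file.path(dir, "window_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$isg)) {
    utils::write.table(run$isg$ranking$lineages,
                       file.path(dir, "isg_lineage_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report_path <- file.path(dir, "report.json")
  report <- run$report
  # stable key order for diff-friendliness
  report <- report[order(names(report))]
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(report_path)
}
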