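# Synthetic screening panel with planted ground truth. The generator
# emulates the structure the analysis assumes in real dependency data: a
# large reference panel plus a small disease group; commonly essential,
# group-selective, reference-selective and neutral genes; a monotone
# logistic map from gene effect to dependency probability; spatially
# autocorrelated copy number along synthetic chromosomes with one
# co-varying segment around a paralog partner; a mutation that abolishes
# one dependency; and an interferon-signature expression shift in the
# disease group. Every random draw flows from one seed through named
# substreams, so panels are reproducible and extending one component
# never perturbs another.

#' Configuration of the synthetic panel generator
#'
#' Defaults encode the study-scale conditions: 500 reference + 4 group
#' lines, 1000 screened genes with 50 commonly essential, 20
#' group-selective and 10 reference-selective genes planted at effect
#' -1.0 over per-observation noise sd 0.2, a logistic effect-to-
#' probability map, five 20-Mb chromosomes at 100-kb gene spacing with
#' AR(1) copy-number autocorrelation, a 5-gene co-varying copy-number
#' block driving a paralog dependency, a pathway mutation abolishing a
#' dependency, and a 4-fold interferon-signature elevation in the group.
#'
#' @param n_reference,n_group,n_genes Panel dimensions.
#' @param n_common,n_group_selective,n_reference_selective Planted class
#'   counts; the remainder is neutral.
#' @param group_effect,common_effect,reference_effect Planted mean gene
#'   effects of the respective classes (dependent lines only).
#' @param noise_sd Per-observation gene-effect noise sd.
#' @param prob_k,prob_x0 Steepness and midpoint of the logistic
#'   effect-to-probability map `p = 1 / (1 + exp(k * (effect - x0)))`.
#' @param prob_noise_sd Independent noise added to probabilities before
#'   clipping to \[0, 1\].
#' @param n_chrom Number of synthetic chromosomes (genes split evenly).
#' @param gene_spacing_bp Distance between adjacent gene midpoints.
#' @param gene_length_bp Gene length (start to end).
#' @param cn_autocorr_genes AR(1) correlation length of background copy
#'   number, in genes.
#' @param cn_sd Marginal sd of background copy number around 2.
#' @param cn_block_halfwidth Planted co-varying block spans the paralog
#'   partner plus this many genes on each side.
#' @param cn_block_sd Per-line sd of the shared block deviation.
#' @param paralog_beta Slope tying the paralog dependency's effect to the
#'   partner's copy number (positive: low copy number = stronger
#'   dependency).
#' @param paralog_base Baseline effect of the paralog dependency.
#' @param n_mutation_features Background binary mutation features.
#' @param mutation_rate Background mutation frequency.
#' @param planted_mutation_freq Frequency of the planted pathway
#'   mutation.
#' @param mutation_loss_beta Effect increase (dependency loss) in lines
#'   carrying the planted mutation.
#' @param isg_shift log2-fold elevation of interferon-signature TPM in
#'   group lines (default 2 = 4-fold).
#' @param expr_meanlog_sd,expr_sdlog Between-gene and within-gene spread
#'   of baseline log TPM.
#' @param n_lineages Reference lineage labels (round-robin); one
#'   single-line lineage (`"teratoma"`) and two `"Engineered"` lines are
#'   always inserted to exercise the exclusion rules.
#' @param missing_frac Fraction of score cells set missing (default 0).
#' @param seed Master seed (required, integer).
#' @return A list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_reference = 500, n_group = 4,
                                   n_genes = 1000,
                                   n_common = 50,
                                   n_group_selective = 20,
                                   n_reference_selective = 10,
                                   group_effect = -1.0,
                                   common_effect = -1.0,
                                   reference_effect = -1.0,
                                   noise_sd = 0.2,
                                   prob_k = 6, prob_x0 = -0.5,
                                   prob_noise_sd = 0.02,
                                   n_chrom = 5,
                                   gene_spacing_bp = 1e5,
                                   gene_length_bp = 2e4,
                                   cn_autocorr_genes = 10,
                                   cn_sd = 0.3,
                                   cn_block_halfwidth = 2,
                                   cn_block_sd = 0.5,
                                   paralog_beta = 0.75,
                                   paralog_base = -0.5,
                                   n_mutation_features = 40,
                                   mutation_rate = 0.05,
                                   planted_mutation_freq = 0.3,
                                   mutation_loss_beta = 1.0,
                                   isg_shift = 2,
                                   expr_meanlog_sd = 1,
                                   expr_sdlog = 0.6,
                                   n_lineages = 20,
                                   missing_frac = 0,
                                   seed = 7L) {
  if (is.null(seed) || length(seed) != 1 || is.na(seed)) {
    stop("an explicit integer seed is required")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  planted <- n_common + n_group_selective + n_reference_selective
  if (planted + 2 > n_genes) {
    stop("planted class counts (plus the two biomarker dependencies) ",
         "exceed n_genes")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (n_group < 2 || n_reference < 2) stop("need >= 2 lines per arm")
  class(cfg) <- "synthetic_panel_config"
  cfg
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}

#' Simulate a screening panel with planted ground truth
#'
#' See [synthetic_panel_config()] for the planted structure. Deterministic
#' given the config seed.
#'
#' @param config A [synthetic_panel_config()].
#' @return A list of class `synthetic_panel` with elements:
#'   `gene_effect`, `dependency_probability` ([score_matrix()]s),
#'   `expression` (`expression_tpm` [feature_matrix()] covering all panel
#'   genes plus the 38 interferon-signature genes), `copy_number`,
#'   `mutations` (feature matrices), `coords` ([gene_coords()]), `meta`
#'   ([panel_metadata()]), and `truth` (list of truth tables: `genes`
#'   with per-gene class, `biomarkers`, `window` anchor/block,
#'   `isg_genes`, `isg_shift`).
#' @export
simulate_panel <- function(config = synthetic_panel_config()) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  cf <- config
  n_lines <- cf$n_reference + cf$n_group
  lines <- sprintf("LINE%04d", seq_len(n_lines))
  group_flag <- c(rep(FALSE, cf$n_reference), rep(TRUE, cf$n_group))
  genes <- sprintf("G%04d", seq_len(cf$n_genes))

  # genomic layout: genes laid sequentially across equal chromosomes
  per_chrom <- ceiling(cf$n_genes / cf$n_chrom)
  chrom <- paste0("chr", rep(seq_len(cf$n_chrom), each = per_chrom))[seq_len(cf$n_genes)]
  pos_in_chrom <- (seq_len(cf$n_genes) - 1) %% per_chrom
  start <- pos_in_chrom * cf$gene_spacing_bp
  coords <- gene_coords(genes, chrom, start, start + cf$gene_length_bp)

  # planted copy-number block: centered mid-chromosome 1
  block_center <- ceiling(per_chrom / 2)
  block_idx <- (block_center - cf$cn_block_halfwidth):
    (block_center + cf$cn_block_halfwidth)
  partner_gene <- genes[block_center]

  # class assignment: planted classes scattered over the remaining genes
  reserved <- c(block_idx)
  classes <- rep("neutral", cf$n_genes)
  assignable <- setdiff(seq_len(cf$n_genes), reserved)
  picks <- with_substream(cf$seed, "classes", {
    sample(assignable,
           cf$n_common + cf$n_group_selective + cf$n_reference_selective + 2)
  })
  i <- 0
  take <- function(n) {
    out <- picks[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  common_idx <- take(cf$n_common)
  group_sel_idx <- take(cf$n_group_selective)
  ref_sel_idx <- take(cf$n_reference_selective)
  paralog_dep_idx <- take(1)
  mutation_dep_idx <- take(1)
  classes[common_idx] <- "common_essential"
  classes[group_sel_idx] <- "group_selective"
  classes[ref_sel_idx] <- "reference_selective"
  classes[paralog_dep_idx] <- "paralog_dependency"
  classes[mutation_dep_idx] <- "mutation_dependency"

  # background copy number: AR(1) along each chromosome, per line
  rho <- exp(-1 / cf$cn_autocorr_genes)
  cn <- with_substream(cf$seed, "copy_number", {
    m <- matrix(0, n_lines, cf$n_genes)
    for (ch in unique(chrom)) {
      j <- which(chrom == ch)
      innov <- matrix(stats::rnorm(n_lines * length(j)), n_lines)
      ar <- matrix(0, n_lines, length(j))
      ar[, 1] <- innov[, 1]
      for (k in seq_along(j)[-1]) {
        ar[, k] <- rho * ar[, k - 1] + sqrt(1 - rho^2) * innov[, k]
      }
      m[, j] <- ar * cf$cn_sd
    }
    # shared segment deviation across the planted block
    seg <- stats::rnorm(n_lines, 0, cf$cn_block_sd)
    m[, block_idx] <- m[, block_idx] + seg
    pmax(2 + m, 0)
  })
  dimnames(cn) <- list(lines, genes)

  # mutation features: background plus one planted pathway mutation
  mut_source <- with_substream(cf$seed, "mutations", {
    src <- genes[setdiff(seq_len(cf$n_genes),
                         c(reserved, picks))][seq_len(cf$n_mutation_features)]
    bg <- matrix(stats::rbinom(n_lines * cf$n_mutation_features, 1,
                               cf$mutation_rate),
                 n_lines, cf$n_mutation_features,
                 dimnames = list(lines, paste0(src, "_any")))
    planted <- stats::rbinom(n_lines, 1, cf$planted_mutation_freq)
    list(bg = bg, planted = planted)
  })
  pathway_gene <- genes[setdiff(seq_len(cf$n_genes), c(reserved, picks))][
    cf$n_mutation_features + 1]
  planted_mut_feature <- paste0(pathway_gene, "_missense")
  mut <- cbind(mut_source$bg,
               matrix(mut_source$planted, ncol = 1,
                      dimnames = list(lines, planted_mut_feature)))

  # gene effects: class means plus planted biomarker couplings plus noise
  mu <- matrix(0, n_lines, cf$n_genes, dimnames = list(lines, genes))
  mu[, common_idx] <- cf$common_effect
  mu[group_flag, group_sel_idx] <- cf$group_effect
  mu[!group_flag, ref_sel_idx] <- cf$reference_effect
  mu[, paralog_dep_idx] <- cf$paralog_base +
    cf$paralog_beta * (cn[, block_center] - 2)
  mu[, mutation_dep_idx] <- cf$common_effect +
    cf$mutation_loss_beta * mut_source$planted
  effect <- with_substream(cf$seed, "effects", {
    mu + matrix(stats::rnorm(n_lines * cf$n_genes, 0, cf$noise_sd),
                n_lines, cf$n_genes)
  })

  # monotone logistic map to dependency probability, plus noise, clipped
  prob <- with_substream(cf$seed, "probability", {
    p <- 1 / (1 + exp(cf$prob_k * (effect - cf$prob_x0)))
    pmin(pmax(p + stats::rnorm(length(p), 0, cf$prob_noise_sd), 0), 1)
  })
  dimnames(prob) <- dimnames(effect)

  if (cf$missing_frac > 0) {
    effect <- with_substream(cf$seed, "missingness", {
      effect[sample.int(length(effect),
                        round(cf$missing_frac * length(effect)))] <- NA
      effect
    })
  }

  # expression: log-normal TPM for panel genes plus the ISG signature,
  # elevated in group lines on the signature genes
  isg <- isg_core_signature()$sets[[1]]
  expr_genes <- c(genes, isg)
  expr <- with_substream(cf$seed, "expression", {
    meanlog <- stats::rnorm(length(expr_genes), 3, cf$expr_meanlog_sd)
    e <- exp(matrix(meanlog, n_lines, length(expr_genes), byrow = TRUE) +
               matrix(stats::rnorm(n_lines * length(expr_genes), 0,
                                   cf$expr_sdlog),
                      n_lines))
    e[group_flag, expr_genes %in% isg] <-
      e[group_flag, expr_genes %in% isg] * 2^cf$isg_shift
    e
  })
  dimnames(expr) <- list(lines, expr_genes)

  # metadata: reference lineages round-robin, plus exclusion-rule bait
  lineage <- rep(NA_character_, n_lines)
  lineage[!group_flag] <- paste0("lineage_",
                                 sprintf("%02d", (seq_len(cf$n_reference) - 1)
                                         %% cf$n_lineages + 1))
  lineage[1:2] <- "Engineered"
  lineage[3] <- "teratoma"
  lineage[group_flag] <- "disease_group"
  meta <- panel_metadata(lines, group_flag, lineage)

  truth <- list(
    genes = data.frame(gene = genes, class = classes,
                       stringsAsFactors = FALSE),
    biomarkers = data.frame(
      dependency_gene = c(genes[paralog_dep_idx], genes[mutation_dep_idx]),
      feature_id = c(partner_gene, planted_mut_feature),
      feature_kind = c("copy_number", "mutation_binary"),
      direction = c("positive", "positive"),
      stringsAsFactors = FALSE),
    window = list(anchor = partner_gene,
                  dependency_gene = genes[paralog_dep_idx],
                  block = genes[block_idx]),
    isg_genes = isg,
    isg_shift = cf$isg_shift)

  structure(list(
    gene_effect = score_matrix(effect, "gene_effect"),
    dependency_probability = score_matrix(prob, "dependency_probability"),
    expression = feature_matrix(expr, "expression_tpm"),
    copy_number = feature_matrix(cn, "copy_number"),
    mutations = feature_matrix(mut, "mutation_binary"),
    coords = coords,
    meta = meta,
    truth = truth,
    config = cf), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(
    "synthetic_panel: %d lines (%d group) x %d genes; planted %d group-selective\n",
    nrow(x$gene_effect$values), sum(x$meta$group_flag),
    ncol(x$gene_effect$values),
    sum(x$truth$genes$class == "group_selective")))
  invisible(x)
}

#' Write all panel files in the standard formats
#'
#' Serializes the panel into the plain-text formats the readers consume:
#' score and feature matrices as CSV, metadata as TSV, coordinates as
#' BED, truth tables as TSV.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_effect = file.path(dir, "gene_effect.csv"),
    dependency_probability = file.path(dir, "dependency_probability.csv"),
    expression = file.path(dir, "expression_tpm.csv"),
    copy_number = file.path(dir, "copy_number.csv"),
    mutations = file.path(dir, "mutations.csv"),
    meta = file.path(dir, "metadata.tsv"),
    coords = file.path(dir, "genes.bed"),
    truth_genes = file.path(dir, "truth_genes.tsv"))
  write_matrix(panel$gene_effect, paths["gene_effect"])
  write_matrix(panel$dependency_probability, paths["dependency_probability"])
  write_matrix(panel$expression, paths["expression"])
  write_matrix(panel$copy_number, paths["copy_number"])
  write_matrix(panel$mutations, paths["mutations"])
  write_panel_metadata(panel$meta, paths["meta"])
  write_gene_coords(panel$coords, paths["coords"])
  utils::write.table(panel$truth$genes, paths["truth_genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Score selectivity calls against planted truth
#'
#' Confusion counts of nominated group-selective genes against the
#' planted classes: sensitivity over planted group-selective genes,
#' specificity over planted neutral genes, and precision over all
#' group-selective calls.
#'
#' @param calls Output of [nominate_selective()] (or any data frame with
#'   `gene` and a status column).
#' @param truth The `genes` truth table of a `synthetic_panel` (columns
#'   `gene`, `class`).
#' @param gate Which status column to score: `"relaxed"` or
#'   `"stringent"`.
#' @return List with `sensitivity`, `specificity`, `precision` and the
#'   integer counts `tp`, `fn`, `fp_neutral`, `tn_neutral`, `fp_total`.
#' @export
evaluate_recovery <- function(calls, truth, gate = c("relaxed",
                                                     "stringent")) {
  gate <- match.arg(gate)
  status_col <- paste0(gate, "_status")
  stopifnot(status_col %in% colnames(calls))
  if (!setequal(calls$gene, truth$gene)) {
    stop("calls and truth cover different gene universes")
  }
  cls <- truth$class[match(calls$gene, truth$gene)]
  called <- calls[[status_col]] == "group_selective"
  planted <- cls == "group_selective"
  neutral <- cls == "neutral"
  tp <- sum(called & planted)
  fn <- sum(!called & planted)
  fp_neutral <- sum(called & neutral)
  tn_neutral <- sum(!called & neutral)
  fp_total <- sum(called & !planted)
  list(sensitivity = if (sum(planted) > 0) tp / sum(planted) else NA_real_,
       specificity = if (sum(neutral) > 0) tn_neutral / sum(neutral) else NA_real_,
       precision = if (tp + fp_total > 0) tp / (tp + fp_total) else NA_real_,
       tp = tp, fn = fn, fp_neutral = fp_neutral,
       tn_neutral = tn_neutral, fp_total = fp_total)
}
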