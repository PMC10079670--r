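# Two-group moderated differential essentiality.
#
# The comparison of a handful of disease lines against hundreds of
# reference lines is variance-starved in the small arm, so per-gene
# variances are shrunk toward a common prior fitted by moment matching on
# the log sample variances (the classic hierarchical scaled-inverse-
# chi-square model). The group-mean difference is reported under the
# conventional "logFC" label of two-group linear models.

#' Per-gene two-group mean difference and pooled variance
#'
#' For every gene, drops cell lines with a missing score, then computes
#' the disease-group minus reference mean difference (`lfc`), the pooled
#' within-group variance `s2`, and the residual degrees of freedom
#' `df = n_group + n_ref - 2`. Genes with fewer than two usable
#' observations in either arm are flagged `usable = FALSE` and excluded
#' from downstream moderation.
#'
#' @param mat A [score_matrix()].
#' @param meta A [panel_metadata()] covering all cell lines in `mat`.
#' @return A data frame with one row per gene: `gene`, `lfc`, `s2`, `df`,
#'   `mean_group`, `mean_ref`, `n_group`, `n_ref`, `usable`.
#' @export
group_difference <- function(mat, meta) {
  stopifnot(inherits(mat, "score_matrix"))
  m <- check_metadata_for_differential(meta, rownames(mat$values))
  grp <- m$group_flag
  v <- mat$values
  vg <- v[grp, , drop = FALSE]
  vr <- v[!grp, , drop = FALSE]
  ng <- colSums(!is.na(vg))
  nr <- colSums(!is.na(vr))
  mean_g <- colMeans(vg, na.rm = TRUE)
  mean_r <- colMeans(vr, na.rm = TRUE)
  # pooled within-group variance; colVars via sums of squares about means
  ss_g <- colSums(sweep(vg, 2, mean_g, "-")^2, na.rm = TRUE)
  ss_r <- colSums(sweep(vr, 2, mean_r, "-")^2, na.rm = TRUE)
  df <- ng + nr - 2
  usable <- ng >= 2 & nr >= 2
  s2 <- ifelse(usable, (ss_g + ss_r) / pmax(df, 1), NA_real_)
  out <- data.frame(gene = colnames(v),
                    lfc = ifelse(usable, mean_g - mean_r, NA_real_),
                    s2 = s2,
                    df = ifelse(usable, df, NA_real_),
                    mean_group = ifelse(ng > 0, mean_g, NA_real_),
                    mean_ref = ifelse(nr > 0, mean_r, NA_real_),
                    n_group = ng, n_ref = nr,
                    usable = usable,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Invert the trigamma function by Newton iteration
#'
#' Solves `trigamma(y) = x` for `y > 0`. Used when fitting the prior
#' degrees of freedom of the variance model. Values of `x` below ~1e-8
#' map to the large-`y` asymptote `y ~ 1/x`.
#'
#' @param x Positive numeric vector.
#' @return Numeric vector `y` with `trigamma(y) = x` to ~1e-10 relative.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= 0) stop("trigamma_inverse needs positive input")
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-12) break
    }
    y
  }, 0)
}

#' Fit the empirical-Bayes variance prior by moment matching
#'
#' Models per-gene sample variances as scaled chi-square draws around a
#' common prior variance `s0_sq` with `d0` prior degrees of freedom, and
#' fits `(d0, s0_sq)` from the mean and variance of `log(s2)`:
#' the excess of `var(log s2)` over `trigamma(df/2)` equals
#' `trigamma(d0/2)`. When there is no excess dispersion the prior is
#' degenerate: `d0 = Inf` and every posterior variance equals `s0_sq`.
#'
#' @param s2 Per-gene sample variances (finite, > 0 entries dominate).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return A list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 10) {
    stop("fewer than 10 usable genes; supply explicit moderation parameters")
  }
  z <- log(s2[ok])
  dfo <- rep_len(df, length(s2))[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  ebar <- mean(e)
  # moment estimate of the excess dispersion of log variances
  evar <- sum((e - ebar)^2) / (length(e) - 1) - mean(trigamma(dfo / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks each usable gene's pooled variance toward the fitted (or
#' supplied) prior, `s2_post = (d0*s0_sq + df*s2) / (d0 + df)`, forms the
#' moderated t `lfc / (sqrt(s2_post) * sqrt(1/n_group + 1/n_ref))`, and
#' derives two-sided p-values from a t reference distribution with
#' `d0 + df` degrees of freedom (normal when `d0 = Inf`). Genes with
#' `s2 = 0` receive the pure-shrinkage posterior `d0*s0_sq / (d0 + df)`
#' rather than an infinite statistic.
#'
#' @param rows Output of [group_difference()].
#' @param params Optional list with `d0` and `s0_sq`; fitted from the data
#'   when absent.
#' @return `rows` with columns `s2_post`, `t_mod`, `P`, `df_total` added,
#'   and the moderation parameters in `attr(, "params")`.
#' @export
empirical_bayes_moderation <- function(rows, params = NULL) {
  stopifnot(all(c("lfc", "s2", "df", "n_group", "n_ref") %in% colnames(rows)))
  use <- rows$usable & is.finite(rows$s2) & is.finite(rows$df)
  if (is.null(params)) {
    params <- fit_variance_prior(rows$s2[use & rows$s2 > 0],
                                 rows$df[use & rows$s2 > 0])
  }
  if (!is.numeric(params$d0) || params$d0 <= 0 ||
      !is.numeric(params$s0_sq) || params$s0_sq <= 0) {
    stop("moderation parameters need d0 > 0 and s0_sq > 0")
  }
  d0 <- params$d0; s0 <- params$s0_sq
  s2_post <- t_mod <- P <- df_total <- rep(NA_real_, nrow(rows))
  if (is.infinite(d0)) {
    s2_post[use] <- s0
    df_total[use] <- Inf
  } else {
    s2_post[use] <- (d0 * s0 + rows$df[use] * rows$s2[use]) / (d0 + rows$df[use])
    df_total[use] <- d0 + rows$df[use]
  }
  sef <- sqrt(1 / rows$n_group + 1 / rows$n_ref)
  t_mod[use] <- rows$lfc[use] / (sef[use] * sqrt(s2_post[use]))
  P[use] <- 2 * stats::pt(-abs(t_mod[use]), df = df_total[use])
  rows$s2_post <- s2_post
  rows$t_mod <- t_mod
  rows$P <- P
  rows$df_total <- df_total
  attr(rows, "params") <- params
  rows
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; missing entries propagate as missing and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values `Q`, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the moderated differential analysis on one score matrix
#'
#' Convenience wrapper: [group_difference()], then
#' [empirical_bayes_moderation()], then [bh_adjust()].
#'
#' @inheritParams group_difference
#' @param params Optional moderation parameters.
#' @return A data frame with `lfc`, `t_mod`, `P`, `Q` and supporting
#'   columns.
#' @export
differential_essentiality <- function(mat, meta, params = NULL) {
  rows <- group_difference(mat, meta)
  rows <- empirical_bayes_moderation(rows, params)
  rows$Q <- bh_adjust(rows$P)
  rows
}

#' Nominate selective dependencies from both score measures
#'
#' Applies the two-stage nomination gates to paired differential tables
#' computed on gene-effect and dependency-probability scores:
#'
#' * relaxed gate: gene-effect `P < relaxed_p` (default 0.02), absolute
#'   gene-effect difference `> relaxed_lfc_effect` (0.4), absolute
#'   probability difference `> relaxed_lfc_prob` (0.3);
#' * stringent gate: `P < stringent_p` (0.01) and absolute difference
#'   `> stringent_lfc` (0.5) on *both* measures.
#'
#' Both gates then apply the direction criteria: a group-selective call
#' requires mean group dependency probability above `prob_cutoff` (0.5)
#' and a positive probability difference; a reference-selective call
#' requires mean group probability at or below the cutoff and a negative
#' difference. Genes present in only one table are flagged and excluded.
#'
#' @param diff_effect Differential table computed on gene-effect scores
#'   (needs `gene`, `lfc`, `P`).
#' @param diff_prob Differential table computed on dependency-probability
#'   scores (needs `gene`, `lfc`, `P`, `mean_group`).
#' @param config A [depsel_config()].
#' @return A data frame with one row per shared gene: `gene`,
#'   `stringent_status`, `relaxed_status` (each `group_selective`,
#'   `reference_selective` or `not_selective`), the gate inputs, and a
#'   `criteria_relaxed` / `criteria_stringent` comma-separated list of
#'   passed criteria. Genes excluded for one-sided coverage are reported
#'   in `attr(, "excluded")`.
#' @export
nominate_selective <- function(diff_effect, diff_prob,
                               config = depsel_config()) {
  shared <- intersect(diff_effect$gene, diff_prob$gene)
  excluded <- union(setdiff(diff_effect$gene, shared),
                    setdiff(diff_prob$gene, shared))
  e <- diff_effect[match(shared, diff_effect$gene), ]
  p <- diff_prob[match(shared, diff_prob$gene), ]

  crit <- list(
    p_effect_relaxed = !is.na(e$P) & e$P < config$relaxed_p,
    lfc_effect_relaxed = !is.na(e$lfc) & abs(e$lfc) > config$relaxed_lfc_effect,
    lfc_prob_relaxed = !is.na(p$lfc) & abs(p$lfc) > config$relaxed_lfc_prob,
    p_effect_stringent = !is.na(e$P) & e$P < config$stringent_p,
    p_prob_stringent = !is.na(p$P) & p$P < config$stringent_p,
    lfc_effect_stringent = !is.na(e$lfc) & abs(e$lfc) > config$stringent_lfc,
    lfc_prob_stringent = !is.na(p$lfc) & abs(p$lfc) > config$stringent_lfc
  )
  relaxed_mag <- crit$p_effect_relaxed & crit$lfc_effect_relaxed &
    crit$lfc_prob_relaxed
  stringent_mag <- crit$p_effect_stringent & crit$p_prob_stringent &
    crit$lfc_effect_stringent & crit$lfc_prob_stringent

  grp_dir <- !is.na(p$mean_group) & p$mean_group > config$prob_cutoff &
    !is.na(p$lfc) & p$lfc > 0
  ref_dir <- !is.na(p$mean_group) & p$mean_group <= config$prob_cutoff &
    !is.na(p$lfc) & p$lfc < 0

  apply_direction <- function(mag, with_direction) {
    status <- rep("not_selective", length(mag))
    if (with_direction) {
      status[mag & grp_dir] <- "group_selective"
      status[mag & ref_dir] <- "reference_selective"
    } else {
      status[mag & !is.na(p$lfc) & p$lfc > 0] <- "group_selective"
      status[mag & !is.na(p$lfc) & p$lfc <= 0] <- "reference_selective"
    }
    status
  }
  relaxed_status <- apply_direction(relaxed_mag, TRUE)
  stringent_status <- apply_direction(stringent_mag,
                                      config$direction_at_stringent)

  passed <- function(idx, crit_names) {
    vapply(idx, function(i) {
      paste(crit_names[vapply(crit_names,
                              function(nm) crit[[nm]][i], TRUE)],
            collapse = ",")
    }, "")
  }
  rel_names <- c("p_effect_relaxed", "lfc_effect_relaxed", "lfc_prob_relaxed")
  str_names <- c("p_effect_stringent", "p_prob_stringent",
                 "lfc_effect_stringent", "lfc_prob_stringent")
  out <- data.frame(gene = shared,
                    lfc_effect = e$lfc, P_effect = e$P,
                    Q_effect = if ("Q" %in% colnames(e)) e$Q else NA_real_,
                    lfc_prob = p$lfc, P_prob = p$P,
                    Q_prob = if ("Q" %in% colnames(p)) p$Q else NA_real_,
                    mean_group_prob = p$mean_group,
                    stringent_status = stringent_status,
                    relaxed_status = relaxed_status,
                    criteria_relaxed = passed(seq_along(shared), rel_names),
                    criteria_stringent = passed(seq_along(shared), str_names),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
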