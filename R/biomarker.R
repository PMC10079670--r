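# Biomarker scan: relate one dependency gene's effect profile to every
# molecular feature (expression, copy number, mutation status) across the
# panel by pairwise-complete Pearson correlation plus a univariate OLS fit.

#' Univariate least-squares fit of dependency on one feature
#'
#' Ordinary least squares of `y` (gene-effect scores) on `x` (one
#' feature), complete pairs only. The slope p-value is the two-sided
#' t-test with `n_obs - 2` degrees of freedom. A perfect fit reports the
#' smallest representable positive p rather than zero.
#'
#' @param x Feature vector.
#' @param y Gene-effect vector, same length.
#' @return List with `slope`, `intercept`, `p_reg`, `n_obs`.
#' @export
univariate_linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) stop("insufficient complete pairs (need >= 3, have ", n, ")")
  x <- x[ok]; y <- y[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("constant predictor")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se == 0) {
    .Machine$double.xmin
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = intercept,
       p_reg = max(p, .Machine$double.xmin), n_obs = n)
}

#' Scan all features of one kind against a dependency profile
#'
#' One association record per feature with at least `min_overlap`
#' pairwise-complete observations against the dependency profile:
#' Pearson `r`, the univariate regression slope/intercept/p, and the
#' observation count. Constant features (or a constant profile over the
#' shared index) yield a record with missing `r` and a reason code rather
#' than an error, so genome-wide scans run to completion.
#'
#' @param dep_profile Named numeric vector of gene-effect scores (names =
#'   cell line ids).
#' @param features A [feature_matrix()].
#' @param min_overlap Minimum complete pairs (default 3).
#' @param decreasing Rank records by decreasing `r` (the copy-number and
#'   expression convention); `FALSE` ranks by increasing `r` (the
#'   mutation convention, where loss-of-dependency correlates rise to the
#'   top).
#' @return Data frame of association records ordered by `r`, with columns
#'   `feature_id`, `feature_kind`, `r`, `n_obs`, `slope`, `intercept`,
#'   `p_reg`, `reason` (empty when defined) and a `rank` column.
#' @export
dependency_feature_correlations <- function(dep_profile, features,
                                            min_overlap = 3,
                                            decreasing = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  shared <- intersect(names(dep_profile), rownames(features$values))
  if (length(shared) == 0) stop("no shared cell lines")
  y <- dep_profile[shared]
  fv <- features$values[shared, , drop = FALSE]
  records <- lapply(colnames(fv), function(f) {
    x <- fv[, f]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    base <- data.frame(feature_id = f, feature_kind = features$kind,
                       r = NA_real_, n_obs = n, slope = NA_real_,
                       intercept = NA_real_, p_reg = NA_real_,
                       reason = "", stringsAsFactors = FALSE)
    if (n < min_overlap) {
      base$reason <- "insufficient_n"
      return(base)
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      base$reason <- "constant"
      return(base)
    }
    base$r <- stats::cor(x[ok], y[ok])
    fit <- univariate_linear_fit(x, y)
    base$slope <- fit$slope
    base$intercept <- fit$intercept
    base$p_reg <- fit$p_reg
    base
  })
  out <- do.call(rbind, records)
  ord <- order(out$r, decreasing = decreasing, na.last = TRUE)
  out <- out[ord, ]
  out$rank <- NA_integer_
  out$rank[!is.na(out$r)] <- seq_len(sum(!is.na(out$r)))
  rownames(out) <- NULL
  out
}
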