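# Independent oracles, written straight from the defining formulas with
# no helpers shared with the package implementation.

# Two-group pooled-variance summary computed elementwise.
oracle_pooled <- function(g, r) {
  n1 <- length(g); n2 <- length(r)
  s2 <- (sum((g - mean(g))^2) + sum((r - mean(r))^2)) / (n1 + n2 - 2)
  list(lfc = mean(g) - mean(r), s2 = s2, df = n1 + n2 - 2)
}

# Full moderated-t pipeline from scratch: moment matching on log sample
# variances with uniroot-based trigamma inversion, posterior shrinkage,
# two-sided t p-values.
oracle_moderated <- function(lfc, s2, df, n1, n2) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - mean(trigamma(df / 2))
  if (excess > 0) {
    d0 <- 2 * uniroot(function(y) trigamma(y) - excess,
                      c(1e-8, 1e8), tol = 1e-14)$root
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2p <- (d0 * s0 + df * s2) / (d0 + df)
    dft <- d0 + df
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
    s2p <- rep(s0, length(s2))
    dft <- rep(Inf, length(s2))
  }
  t <- lfc / (sqrt(s2p) * sqrt(1 / n1 + 1 / n2))
  list(d0 = d0, s0_sq = s0, t = t, P = 2 * pt(-abs(t), dft))
}

# Benjamini-Hochberg by literal step-up enumeration.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  ranked <- p[o] * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  for (i in seq_len(n)) q[i] <- min(ranked[i:n], 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Running-sum enrichment score by explicit position-by-position walk.
oracle_es <- function(metric, set, weight = 1) {
  genes <- names(metric)
  o <- order(metric, decreasing = TRUE)
  genes <- genes[o]; metric <- metric[o]
  hit <- genes %in% set
  n <- length(genes); nh <- sum(hit)
  w <- abs(metric)^weight
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- nh }
  run <- 0
  vals <- numeric(n)
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) unname(w[i]) / tot else -1 / (n - nh)
    vals[i] <- run
  }
  top <- max(vals)
  bottom <- min(c(vals, 0))
  # positive deviation wins a (numerically) exact tie
  if (top >= -bottom - 1e-12) top else bottom
}

# Upper-tail hypergeometric by enumerating every possible list.
oracle_hypergeom <- function(N, K, n, k) {
  universe <- seq_len(N)
  set <- seq_len(K)
  lists <- combn(universe, n)
  mean(apply(lists, 2, function(l) sum(l %in% set) >= k))
}

# ZMAD by a naive per-gene loop.
oracle_zmad <- function(v, mode = "mean") {
  z <- v
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    ctr <- median(x)
    scl <- if (mode == "mean") mean(abs(x - ctr)) else median(abs(x - ctr))
    z[, j] <- (x - ctr) / scl
  }
  z
}

# Simple-regression closed form evaluated independently.
oracle_ols <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2)) / sqrt(sum((x - mean(x))^2))
  list(slope = b, intercept = a,
       p = 2 * pt(-abs(b / se), n - 2), n = n)
}

# Connected components by brute-force label propagation over the
# thresholded pair scan.
oracle_components <- function(r, threshold) {
  genes <- colnames(r)
  labels <- seq_along(genes)
  repeat {
    changed <- FALSE
    for (i in seq_along(genes)) for (j in seq_along(genes)) {
      if (i != j && !is.na(r[i, j]) && r[i, j] >= threshold &&
          labels[j] != labels[i]) {
        new <- min(labels[i], labels[j])
        labels[labels == labels[i] | labels == labels[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(genes, labels)
}

# Small deterministic score matrix for reader/transform tests.
toy_score_matrix <- function(n_lines = 6, n_genes = 4, seed = 42,
                             measure = "gene_effect") {
  set.seed(seed)
  v <- matrix(rnorm(n_lines * n_genes), n_lines,
              dimnames = list(sprintf("CL%02d", seq_len(n_lines)),
                              sprintf("GENE%02d", seq_len(n_genes))))
  if (measure == "dependency_probability") v <- plogis(v)
  score_matrix(v, measure)
}
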