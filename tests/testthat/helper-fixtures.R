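# Shared fixtures and independent oracles. Oracles are deliberately
# brute-force (enumeration / normal equations / naive agglomeration) and
# never reuse the code paths they check.

small_cohort <- function(n_per_group = 10L, seed = 1L, ...) {
  generate_cohort(n_per_group = n_per_group, seed = seed, ...)
}

small_tables <- function(meta = small_cohort(), seed = 1L, ...) {
  defaults <- list(meta = meta, n_cell_mets = 40L, n_media_mets = 30L,
                   n_shared = 20L, censor_fraction = 0.05, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(generate_tables, args)
}

# a tiny hand-made abundance table
toy_table <- function(values, kind = "media", batch = NULL, protein = NULL) {
  if (is.null(batch)) batch <- rep(1L, nrow(values))
  abundance_table(values, kind, batch, protein_conc = protein)
}

# ---- oracles -------------------------------------------------------------

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# OLS through the normal equations
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# trigamma inversion by bisection
oracle_trigamma_inverse <- function(x, lo = 1e-8, hi = 1e8) {
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# 2x2 Fisher exact p by full enumeration over fixed margins
oracle_fisher_2x2 <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(a) {
    choose(r[1], a) * choose(r[2], cs[1] - a) / choose(n, cs[1])
  }
  a_range <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  probs <- vapply(a_range, prob, numeric(1))
  p_obs <- prob(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2L, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# complete-linkage agglomeration by naive repeated scanning; returns the
# sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in seq((i + 1), length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# exact Clopper-Pearson interval from the beta quantile representation
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# Pearson correlation p-value from first principles
oracle_pearson_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), n - 2)
}
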