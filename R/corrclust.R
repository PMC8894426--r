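# Correlation structure of significant ratio features (with significance
# masking and negative-block detection) and unsupervised sample
# clustering under correlation distance with complete linkage.

#' Pairwise feature correlations with significance mask
#'
#' Pearson (default) or Spearman correlations between features, with
#' two-sided p-values (t transform of r for Pearson, the rank-based
#' reference for Spearman) and a significance mask at p < 0.05, the mask
#' used to draw only significant entries in correlation plots.
#'
#' @param values samples x features matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha mask threshold.
#' @return a `correlation_report`: list with `r`, `p`, `mask`,
#'   `feature_ids`, `method`, `n`.
#' @export
correlation_matrix <- function(values, method = c("pearson", "spearman"),
                               alpha = 0.05) {
  method <- match.arg(method)
  n <- nrow(values)
  if (n < 3L) stop("correlation analysis needs at least 3 samples")
  sdv <- apply(values, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(sdv == 0)),
            call. = FALSE)
    values <- values[, sdv > 0, drop = FALSE]
  }
  if (method == "spearman") values <- apply(values, 2L, rank)
  r <- stats::cor(values)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(r = r, p = p, mask = p < alpha,
                 feature_ids = colnames(values), method = method, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report: %s> %d features over %d samples, %d significant off-diagonal pairs\n",
              x$method, length(x$feature_ids), x$n,
              (sum(x$mask) - length(x$feature_ids)) / 2))
  invisible(x)
}

#' Detect negative correlation blocks
#'
#' Features are ordered by hierarchical clustering of the correlation
#' matrix (distance 1 - r, complete linkage) and cut at distance 1
#' (correlation zero), grouping positively correlated features. Every
#' pair of clusters at least `min_block_size` features each defines a
#' contiguous off-diagonal block; blocks whose mean significant
#' correlation is at most `mean_r_threshold` are reported, ranked by
#' |mean r|.
#'
#' @param report a `correlation_report`.
#' @param min_block_size minimum features per cluster on both sides.
#' @param mean_r_threshold negative threshold on the block's mean
#'   significant correlation.
#' @return data.frame of blocks (possibly empty) with cluster member
#'   lists in the `members_a` / `members_b` attributes of each row's
#'   entry in `attr(, "members")`.
#' @export
detect_negative_blocks <- function(report, min_block_size = 3L,
                                   mean_r_threshold = -0.3) {
  stopifnot(inherits(report, "correlation_report"))
  ids <- report$feature_ids
  hc <- stats::hclust(stats::as.dist(1 - report$r), method = "complete")
  cl <- stats::cutree(hc, h = 1)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_block_size])
  rows <- list(); members <- list()
  if (length(big) >= 2L) {
    for (i in seq_along(big)[-length(big)]) for (j in seq((i + 1), length(big))) {
      a <- ids[cl == big[i]]; b <- ids[cl == big[j]]
      sub_r <- report$r[a, b, drop = FALSE]
      sub_m <- report$mask[a, b, drop = FALSE]
      if (!any(sub_m)) next
      mr <- mean(sub_r[sub_m])
      if (mr <= mean_r_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_a = big[i], cluster_b = big[j],
          size_a = length(a), size_b = length(b),
          n_significant = sum(sub_m), mean_r = mr)
        members[[length(members) + 1L]] <- list(a = a, b = b)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      size_a = integer(), size_b = integer(),
                      n_significant = integer(), mean_r = numeric())
  } else {
    out <- do.call(rbind, rows)
    ord <- order(-abs(out$mean_r))
    out <- out[ord, , drop = FALSE]
    members <- members[ord]
    rownames(out) <- NULL
  }
  out$block_id <- seq_len(nrow(out))
  attr(out, "members") <- members
  attr(out, "order") <- ids[hc$order]
  out
}

#' Cluster samples under correlation distance
#'
#' Pairwise sample distance is 1 minus the Pearson correlation between
#' the samples' feature profiles; agglomeration is complete linkage.
#' Samples with constant profiles (correlation undefined) are dropped
#' with a warning.
#'
#' @param values samples x features matrix (significant features).
#' @param labels phenotype label per sample (named by sample id or
#'   aligned with rows).
#' @return a `cluster_result`: list with the `hclust` tree, `labels`,
#'   `leaf_order` (sample ids in dendrogram order).
#' @export
hcluster_samples <- function(values, labels) {
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("sample clustering needs >= 2 samples and >= 2 features")
  labels <- if (!is.null(names(labels))) labels[rownames(values)] else
    stats::setNames(labels, rownames(values))
  const <- apply(values, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant sample profile(s): %s",
                    sum(const), paste(rownames(values)[const], collapse = ", ")),
            call. = FALSE)
    values <- values[!const, , drop = FALSE]
    labels <- labels[!const]
  }
  d <- stats::as.dist(1 - stats::cor(t(values)))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, labels = labels,
                 leaf_order = rownames(values)[hc$order]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d samples, complete linkage on correlation distance\n",
              length(x$labels)))
  invisible(x)
}

#' Samples disagreeing with their cluster's majority phenotype
#'
#' Cuts the tree at `k` clusters, assigns each cluster its majority
#' phenotype (ties count every modal label as majority, i.e. break
#' toward "not misclassified") and returns the samples whose label
#' differs from their cluster's majority.
#'
#' @param cluster a `cluster_result`.
#' @param k number of clusters to cut at.
#' @return character vector of sample ids (sorted; possibly empty).
#' @export
misclassified_samples <- function(cluster, k) {
  stopifnot(inherits(cluster, "cluster_result"))
  n <- length(cluster$labels)
  if (k > n) stop("k cannot exceed the number of samples")
  assign <- stats::cutree(cluster$hclust, k = k)
  bad <- character()
  for (cl in unique(assign)) {
    ids <- names(assign)[assign == cl]
    tab <- table(as.character(cluster$labels[ids]))
    modal <- names(tab)[tab == max(tab)]
    bad <- c(bad, ids[!as.character(cluster$labels[ids]) %in% modal])
  }
  sort(bad)
}
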