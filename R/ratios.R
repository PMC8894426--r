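# Ratio feature construction: cells-over-media ratios for metabolites
# detected in both matrices, and all pairwise ratios over a prioritized
# metabolite panel (metabotyping). Ratios are differences of natural-log
# values taken *before* center-scaling (a difference of logs is the log
# of the ratio); the resulting features are then center-scaled
# themselves for testing and clustering.

#' Metabolites shared between two matrices
#'
#' @param cells,media `normalized_table`s over the same samples.
#' @return sorted character vector of shared metabolite ids.
#' @export
shared_metabolites <- function(cells, media) {
  if (!setequal(rownames(cells$log_values), rownames(media$log_values)))
    stop("cells and media tables must cover the same samples")
  sort(intersect(colnames(cells$log_values), colnames(media$log_values)))
}

#' Cells-over-media ratio features
#'
#' One feature per shared metabolite: the per-sample difference of
#' natural-log normalized abundances, cells minus media (i.e. the log of
#' the cells/media ratio). Features are center-scaled for testing.
#'
#' @param cells,media `normalized_table`s over the same samples.
#' @return a `ratio_table`: list with `values` (log-ratio scale),
#'   `scaled` (per-feature mean 0 / sd 1), `provenance`, `feature_ids`.
#' @export
cell_media_ratios <- function(cells, media) {
  shared <- shared_metabolites(cells, media)
  if (!length(shared)) stop("no shared metabolites between cells and media")
  samp <- rownames(cells$log_values)
  vals <- cells$log_values[samp, shared, drop = FALSE] -
    media$log_values[samp, shared, drop = FALSE]
  colnames(vals) <- paste0(shared, "@cells/", shared, "@media")
  scaled <- center_scale_columns(vals, context = "ratio feature")
  structure(list(values = vals, scaled = scaled,
                 provenance = "CELL_OVER_MEDIA",
                 feature_ids = colnames(vals),
                 n_detected = length(shared)),
            class = "ratio_table")
}

#' Pairwise panel ratio features (metabotyping)
#'
#' For the panel metabolites detected in a matrix, one feature per
#' unordered pair `(A, B)` with `A < B` lexicographically: the per-sample
#' log ratio `log A - log B`. Panel names absent from the matrix are
#' dropped (and reported via attributes).
#'
#' @param norm a `normalized_table`.
#' @param panel character vector of panel metabolite names.
#' @return a `ratio_table` with `n_detected` panel metabolites and
#'   `choose(n_detected, 2)` features.
#' @export
pairwise_panel_ratios <- function(norm, panel) {
  detected <- sort(intersect(panel, colnames(norm$log_values)))
  missing <- setdiff(panel, detected)
  if (length(detected) < 2L)
    stop(sprintf("fewer than 2 panel metabolites detected; missing: %s",
                 paste(missing, collapse = ", ")))
  pairs <- utils::combn(detected, 2L)
  vals <- norm$log_values[, pairs[1, ], drop = FALSE] -
    norm$log_values[, pairs[2, ], drop = FALSE]
  colnames(vals) <- sprintf("%s/%s@%s", pairs[1, ], pairs[2, ], norm$kind)
  scaled <- center_scale_columns(vals, context = "ratio feature")
  structure(list(values = vals, scaled = scaled,
                 provenance = "PANEL_PAIRWISE",
                 feature_ids = colnames(vals),
                 n_detected = length(detected),
                 panel_missing = missing),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("<ratio_table: %s> %d samples x %d features (%d metabolites detected)\n",
              x$provenance, nrow(x$values), ncol(x$values), x$n_detected))
  invisible(x)
}

#' Number of pairwise ratio tests
#'
#' `n * (n - 1) / 2` unordered pairs from `n` detected panel metabolites
#' (38 detected metabolites give 703 tests, 39 give 741).
#'
#' @param n_detected number of detected panel metabolites.
#' @return integer pair count.
#' @export
count_ratio_tests <- function(n_detected) {
  if (any(n_detected < 0)) stop("`n_detected` must be non-negative")
  as.integer(n_detected * (n_detected - 1) / 2)
}
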