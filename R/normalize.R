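# Normalization chain for untargeted metabolomics peak areas:
# batch median scaling -> (cells only: protein normalization) ->
# minimum-value imputation -> natural log -> per-metabolite center-scale.

#' Batch median scaling
#'
#' For each metabolite, observed values inside each instrument batch are
#' divided by that batch's median, giving every (metabolite, batch) group
#' a median of one. Missing values are untouched; medians see observed
#' values only (imputation happens later, downstream of scaling).
#'
#' @param raw an [abundance_table].
#' @return the table with scaled values.
#' @export
batch_median_scale <- function(raw) {
  stopifnot(inherits(raw, "abundance_table"))
  v <- raw$values
  for (b in unique(raw$batch)) {
    idx <- raw$batch == b
    med <- apply(v[idx, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    dead <- !is.finite(med)
    if (any(dead))
      stop(sprintf("metabolite %s entirely missing in batch %s",
                   colnames(v)[which(dead)[1]], b))
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2L, med, "/")
  }
  raw$values <- v
  raw
}

#' Protein normalization (cells matrix only)
#'
#' Each sample's observed values are divided by that sample's protein
#' concentration, then each metabolite is rescaled so its overall median
#' of observed values is one again. Applied after batch scaling and
#' before imputation.
#'
#' @param table a batch-scaled cells [abundance_table].
#' @return the table with protein-normalized values.
#' @export
protein_normalize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "cells")
    stop(sprintf("protein normalization is defined for the cells matrix, not %s",
                 table$kind))
  pc <- table$protein_conc
  if (is.null(pc) || any(pc <= 0))
    stop("protein concentration must be positive for every sample")
  v <- sweep(table$values, 1L, pc, "/")
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  table$values <- sweep(v, 2L, med, "/")
  table
}

#' Minimum-value imputation
#'
#' Each missing entry is replaced by that metabolite's minimum observed
#' (scaled) value across all batches, the standard proxy for a
#' below-detection-limit measurement. The returned table carries an
#' `imputed` logical mask marking exactly the originally missing entries.
#'
#' @param table a median-scaled [abundance_table].
#' @return the table with no missing values and an `imputed` mask field.
#' @export
impute_min <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  mask <- is.na(v)
  if (any(colSums(!mask) == 0L))
    stop("metabolite with no observed value cannot be imputed")
  mins <- apply(v, 2L, min, na.rm = TRUE)
  for (j in which(colSums(mask) > 0L)) v[mask[, j], j] <- mins[j]
  table$values <- v
  table$imputed <- mask
  table
}

#' Natural-log transform and center-scale
#'
#' Values (strictly positive after imputation) are natural-log
#' transformed, then each metabolite is centered to mean 0 and scaled to
#' sample standard deviation (n - 1) 1. Metabolites left constant (zero
#' variance, e.g. fully imputed) are dropped with a warning and recorded.
#'
#' @param table an imputed [abundance_table].
#' @return a `normalized_table`: list with `kind`, `log_values` (natural
#'   log scale, pre-scaling), `scaled_values` (mean 0 / sd 1 per
#'   metabolite), `imputed` mask, `batch`, and `dropped` metabolite ids.
#' @export
log_center_scale <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (any(table$values <= 0, na.rm = TRUE) || anyNA(table$values))
    stop("log transform needs strictly positive, complete values (impute first)")
  logv <- log(table$values)
  scaled <- center_scale_columns(logv, context = "metabolite")
  dropped <- attr(scaled, "dropped")
  attr(scaled, "dropped") <- NULL
  keep <- setdiff(colnames(logv), dropped)
  mask <- table$imputed
  if (is.null(mask)) mask <- matrix(FALSE, nrow(logv), ncol(logv),
                                    dimnames = dimnames(logv))
  structure(list(kind = table$kind,
                 log_values = logv[, keep, drop = FALSE],
                 scaled_values = scaled,
                 imputed = mask[, keep, drop = FALSE],
                 batch = table$batch,
                 dropped = dropped),
            class = "normalized_table")
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("<normalized_table: %s> %d samples x %d metabolites (%d dropped), %d imputed entries\n",
              x$kind, nrow(x$scaled_values), ncol(x$scaled_values),
              length(x$dropped), sum(x$imputed)))
  invisible(x)
}

#' Full normalization chain for one matrix
#'
#' Cells: batch median scaling, protein normalization, minimum-value
#' imputation, natural log, center-scale. Media and blank: the same chain
#' without the protein step.
#'
#' @param raw an [abundance_table].
#' @return a `normalized_table` (see [log_center_scale()]).
#' @examples
#' meta <- generate_cohort(seed = 1)
#' tabs <- generate_tables(meta, n_cell_mets = 40, n_media_mets = 30,
#'                         n_shared = 20, seed = 1)
#' norm <- normalize_matrix(tabs$cells)
#' colMeans(norm$scaled_values)[1:3]  # ~0 by construction
#' @export
normalize_matrix <- function(raw) {
  stopifnot(inherits(raw, "abundance_table"))
  x <- batch_median_scale(raw)
  if (x$kind == "cells") x <- protein_normalize(x)
  x <- impute_min(x)
  log_center_scale(x)
}
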