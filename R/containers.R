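#' Phenotype group and sex level sets
#'
#' The three phenotype groups contrasted by the study design: autism
#' spectrum disorder and/or developmental delay without cancer, cancer
#' without ASD/DD, and both phenotypes.
#' @export
GROUP_LEVELS <- c("ASD_DD", "CANCER", "CANCER_ASD_DD")

#' @rdname GROUP_LEVELS
#' @export
SEX_LEVELS <- c("F", "M")

MATRIX_KINDS <- c("cells", "media", "blank")

#' Construct a raw abundance table
#'
#' A light container for one matrix (cell pellets, spent media, or blank
#' media) of raw, strictly positive peak areas with `NA` marking values
#' below the detection limit.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns,
#'   with complete dimnames. Observed values must be strictly positive;
#'   `NA` encodes a missing (censored) measurement.
#' @param kind one of `"cells"`, `"media"`, `"blank"`.
#' @param batch integer instrument-batch label per sample.
#' @param protein_conc positive protein concentration per sample; required
#'   for (and only allowed on) the `"cells"` matrix.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, kind, batch, protein_conc = NULL) {
  kind <- match.arg(kind, MATRIX_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and metabolite ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in abundance table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids in abundance table")
  if (any(values <= 0, na.rm = TRUE))
    stop("observed abundances must be strictly positive")
  all_missing <- colSums(!is.na(values)) == 0L
  if (any(all_missing))
    stop(sprintf("metabolite(s) entirely missing: %s",
                 paste(utils::head(colnames(values)[all_missing], 5L), collapse = ", ")))
  batch <- as.integer(batch)
  if (length(batch) != nrow(values))
    stop("`batch` must have one entry per sample")
  if (kind == "cells") {
    if (is.null(protein_conc))
      stop("cells matrix requires `protein_conc`")
    protein_conc <- as.numeric(protein_conc)
    if (length(protein_conc) != nrow(values) || any(!is.finite(protein_conc)) ||
        any(protein_conc <= 0))
      stop("`protein_conc` must be positive and finite for every sample")
    names(protein_conc) <- rownames(values)
  } else if (!is.null(protein_conc)) {
    stop(sprintf("`protein_conc` is only defined for the cells matrix, not %s", kind))
  }
  names(batch) <- rownames(values)
  structure(list(values = values, kind = kind, batch = batch,
                 protein_conc = protein_conc),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table: %s> %d samples x %d metabolites, %d batches, %d missing (%.1f%%)\n",
              x$kind, nrow(x$values), ncol(x$values), length(unique(x$batch)),
              sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Validate a sample metadata table
#'
#' Checks the cohort description used throughout the pipeline: unique
#' sample ids, phenotype group in [GROUP_LEVELS], sex in [SEX_LEVELS],
#' positive age at consent, integer batch labels.
#'
#' @param meta data.frame with columns `sample_id`, `group`, `sex`,
#'   `age_at_consent`, `batch`.
#' @return the validated data.frame with `group` and `sex` as factors.
#' @export
validate_metadata <- function(meta) {
  req <- c("sample_id", "group", "sex", "age_at_consent", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  grp <- toupper(gsub("[ /-]", "_", trimws(as.character(meta$group))))
  bad <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(GROUP_LEVELS, collapse = ", ")))
  sex <- toupper(trimws(as.character(meta$sex)))
  bad <- setdiff(unique(sex), SEX_LEVELS)
  if (length(bad))
    stop(sprintf("unknown sex code(s) %s; allowed: %s",
                 paste(bad, collapse = ", "), paste(SEX_LEVELS, collapse = ", ")))
  if (any(!is.finite(meta$age_at_consent)) || any(meta$age_at_consent <= 0))
    stop("age_at_consent must be positive and finite")
  meta$sample_id <- as.character(meta$sample_id)
  meta$group <- factor(grp, levels = GROUP_LEVELS)
  meta$sex <- factor(sex, levels = SEX_LEVELS)
  meta$batch <- as.integer(meta$batch)
  meta
}
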