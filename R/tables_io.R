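# Readers and writers for every tabular artifact. All writers use fixed
# column order and fixed decimal formatting so outputs are diffable and
# re-running a pipeline yields byte-identical files.

ANNOT_COLS <- c("batch", "protein_conc")

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a raw abundance table
#'
#' Wide orientation: one row per sample, first column `sample_id`, then
#' the annotation columns `batch` (and `protein_conc` for cells), then
#' one column per metabolite. Missing values are written as `NA`.
#'
#' @param x an [abundance_table].
#' @param path output path; `.csv` selects comma, anything else tab.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(sample_id = rownames(x$values), batch = x$batch,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (x$kind == "cells") df$protein_conc <- fmt_num(x$protein_conc)
  vals <- apply(x$values, 2L, fmt_num)
  df <- cbind(df, as.data.frame(vals, check.names = FALSE,
                                stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a raw abundance table
#'
#' Inverse of [write_abundance_table()]. Empty cells and `NA` denote
#' missing values; duplicated metabolite columns are rejected; any
#' non-numeric abundance cell is reported with its row and column. If the
#' first header token is `metabolite_id` the file is in long (metabolite
#' -major) orientation and is transposed on read.
#'
#' @param path input path.
#' @param kind matrix kind (`"cells"`, `"media"`, `"blank"`).
#' @return an [abundance_table].
#' @export
read_abundance_table <- function(path, kind) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  sep <- sep_for(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop(sprintf("duplicated column header(s): %s",
                 paste(unique(header[duplicated(header)]), collapse = ", ")))
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (header[1] == "metabolite_id") {
    ids <- df[[1]]
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- ids
    df <- data.frame(sample_id = rownames(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE,
                                  stringsAsFactors = FALSE))
  }
  met_cols <- setdiff(names(df), c("sample_id", ANNOT_COLS))
  vals <- matrix(NA_real_, nrow(df), length(met_cols),
                 dimnames = list(df$sample_id, met_cols))
  for (j in seq_along(met_cols)) {
    cell <- df[[met_cols[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at sample %s, metabolite %s",
                   cell[bad[1]], df$sample_id[bad[1]], met_cols[j]))
    vals[, j] <- num
  }
  batch <- if ("batch" %in% names(df)) as.integer(df$batch) else rep(1L, nrow(df))
  protein <- if ("protein_conc" %in% names(df)) as.numeric(df$protein_conc) else NULL
  abundance_table(vals, kind, batch, protein_conc = protein)
}

#' Read or write sample metadata
#'
#' Group and sex labels are case-folded (`cancer` -> `CANCER`); unknown
#' labels raise an error listing the allowed values.
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  out <- data.frame(sample_id = meta$sample_id,
                    group = as.character(meta$group),
                    sex = as.character(meta$sex),
                    age_at_consent = fmt_num(meta$age_at_consent),
                    batch = meta$batch)
  utils::write.table(out, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metabolite panel file
#'
#' One metabolite name per line; `#` starts a comment; blank lines are
#' ignored; names must be unique after whitespace trimming.
#'
#' @param path file path.
#' @return character vector of panel metabolite names.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (anyDuplicated(lines))
    stop(sprintf("duplicate panel name(s): %s",
                 paste(unique(lines[duplicated(lines)]), collapse = ", ")))
  lines
}

#' @rdname read_panel
#' @param panel character vector of metabolite names.
#' @export
write_panel <- function(panel, path) {
  writeLines(c("# metabolite panel, one name per line", panel), path)
  invisible(path)
}

config_defaults <- function() {
  list(alpha_adjusted = 0.05,
       pca_variance_threshold = 0.95,
       corr_removal_threshold = 0.90,
       logitboost_iter_grid = c(11L, 21L, 31L),
       positive_class = "CANCER",
       seed = 1L,
       n_per_group = 10L, n_female_per_group = 7L,
       age_range = c(2, 59), n_batches = 2L,
       n_cell_mets = 645L, n_media_mets = 489L, n_shared = 386L,
       batch_sd = 0.3, noise_sd = 0.3, sample_sd = 0,
       censor_fraction = 0.05, panel_size = 43L)
}

#' Load a pipeline configuration
#'
#' Flat key/value YAML. Unknown keys warn (never fail), missing keys take
#' their documented defaults, and out-of-range values raise a validation
#' error.
#'
#' @param path path to a YAML config, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return validated config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  user[names(overrides)] <- overrides
  extra_keys <- c("panel_path", "out_dir", "effects", "ratio_effects")
  unknown <- setdiff(names(user), c(names(cfg), extra_keys))
  if (length(unknown))
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  keep <- intersect(names(user), c(names(cfg), extra_keys))
  cfg[keep] <- user[keep]
  if (cfg$alpha_adjusted <= 0 || cfg$alpha_adjusted > 1)
    stop("config: `alpha_adjusted` must lie in (0, 1]")
  if (cfg$pca_variance_threshold <= 0 || cfg$pca_variance_threshold > 1)
    stop("config: `pca_variance_threshold` must lie in (0, 1]")
  if (cfg$corr_removal_threshold < 0 || cfg$corr_removal_threshold > 1)
    stop("config: `corr_removal_threshold` must lie in [0, 1]")
  if (any(cfg$logitboost_iter_grid < 1))
    stop("config: `logitboost_iter_grid` must contain positive integers")
  if (!cfg$positive_class %in% GROUP_LEVELS)
    stop(sprintf("config: `positive_class` must be one of %s",
                 paste(GROUP_LEVELS, collapse = ", ")))
  if (!is.null(cfg$panel_path) && !file.exists(cfg$panel_path))
    stop(sprintf("config: panel file does not exist: %s", cfg$panel_path))
  cfg$logitboost_iter_grid <- as.integer(sort(unlist(cfg$logitboost_iter_grid)))
  cfg
}

#' Write differential-abundance results
#'
#' Fixed column order (`feature`, `coef`, `se`, `t_ordinary`,
#' `t_moderated`, `df_total`, `p_raw`, `p_adj`, `significant`) and fixed
#' formatting, so identical results yield byte-identical files.
#' @param res a `diff_result` data.frame from [moderated_test()].
#' @param path output path.
#' @export
write_diff_results <- function(res, path) {
  cols <- c("feature", "coef", "se", "t_ordinary", "t_moderated",
            "df_total", "p_raw", "p_adj", "significant")
  out <- res[, cols]
  for (cl in setdiff(cols, c("feature", "significant")))
    out[[cl]] <- fmt_num(out[[cl]])
  utils::write.table(out, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a classification report
#' @param report a `classification_report` (see [confusion_report()]).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# accuracy\t%s", fmt_num(report$overall_accuracy)), con)
  writeLines(sprintf("# ci95\t%s\t%s", fmt_num(report$ci95[1]),
                     fmt_num(report$ci95[2])), con)
  writeLines(sprintf("# nir\t%s\tp_vs_nir\t%s", fmt_num(report$nir),
                     fmt_num(report$p_vs_nir)), con)
  writeLines(sprintf("# sensitivity\t%s", paste(fmt_num(report$sensitivity),
                                                collapse = "\t")), con)
  writeLines(sprintf("# specificity\t%s", paste(fmt_num(report$specificity),
                                                collapse = "\t")), con)
  utils::write.table(as.data.frame.matrix(report$confusion), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, seed, config echo and an md5 content hash
#' for every emitted file; two runs with the same config and seed must
#' produce identical manifests.
#'
#' @param dir run output directory.
#' @param config config list.
#' @param files character vector of file paths (inside `dir`) to hash.
#' @param extra optional named character vector of extra fields.
#' @export
write_manifest <- function(dir, config, files, extra = character()) {
  path <- file.path(dir, "manifest.txt")
  lines <- c(sprintf("package\tmetabophen %s",
                     as.character(utils::packageVersion("metabophen"))),
             sprintf("seed\t%s", config$seed))
  cfg <- config[order(names(config))]
  lines <- c(lines, vapply(names(cfg), function(k)
    sprintf("config.%s\t%s", k, paste(format(cfg[[k]]), collapse = ",")),
    character(1)))
  if (length(extra))
    lines <- c(lines, sprintf("%s\t%s", names(extra), extra))
  hashes <- tools::md5sum(files)
  lines <- c(lines, sprintf("file\t%s\t%s", basename(files), unname(hashes)))
  writeLines(lines, path)
  invisible(path)
}
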