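# End-to-end orchestration: simulate (or load) -> normalize -> four
# differential-abundance arms (cells, media, cells/media ratios,
# metabotype ratios) -> correlation/cluster analyses -> classification
# performance grid, with deterministic artifacts and a hashed manifest.

#' Build a synthetic metabotyping panel
#'
#' Selects panel metabolite names from the generated tables so that the
#' panel exercises the detection bookkeeping: shared metabolites
#' detected in both matrices, one media-only metabolite, and a few names
#' absent everywhere. With the default sizes the panel holds 43 names of
#' which 38 are detected in cells and 39 in media.
#'
#' @param tables output of [generate_tables()].
#' @param size panel size.
#' @param n_absent names absent from both matrices.
#' @param n_media_only media-only metabolites included.
#' @return character vector of panel names.
#' @export
synthetic_panel <- function(tables, size = 43L, n_absent = 4L,
                            n_media_only = 1L) {
  shared <- intersect(colnames(tables$cells$values),
                      colnames(tables$media$values))
  media_only <- setdiff(colnames(tables$media$values), shared)
  n_shared <- size - n_absent - n_media_only
  if (n_shared > length(shared) || n_media_only > length(media_only))
    stop("tables too small for the requested panel composition")
  c(shared[seq_len(n_shared)],
    media_only[seq_len(n_media_only)],
    sprintf("panel_absent_%02d", seq_len(n_absent)))
}

# Significant feature ids for both groupings, tested on the log scale.
# `keep` restricts the lists to features that survived center-scaling
# (constant features are dropped there and cannot feed the classifier).
sig_sets <- function(values, meta, alpha, keep = colnames(values)) {
  two <- diff_abundance(values, meta, GROUP_LEVELS[1:2], alpha = alpha)
  three <- diff_abundance(values, meta, "three_group", alpha = alpha)
  list(significant = list(
         two_group = intersect(two$feature[two$significant], keep),
         three_group = intersect(three$feature[three$significant], keep)),
       diff = list(two_group = two, three_group = three))
}

#' Run the full pipeline
#'
#' Simulates a cohort and two-matrix abundance tables (or loads them
#' from the paths in `config`), normalizes each matrix, runs the four
#' analysis arms (single metabolites in cells and in media, cells/media
#' ratios over shared metabolites, pairwise panel metabotype ratios),
#' feeds each arm's significant features into correlation/cluster
#' analysis and the LOOCV LogitBoost performance grid, and writes every
#' artifact plus a hashed manifest to `out_dir`.
#'
#' @param config configuration list from [load_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory results (`meta`,
#'   `tables`, `norm`, `arms`, `corr`, `blocks`, `clusters`,
#'   `misclassified`, `performance`, `files`).
#' @export
run_all <- function(config = load_config(), out_dir = tempfile("metabophen_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  alpha <- config$alpha_adjusted

  # --- simulate or load ---------------------------------------------------
  if (!is.null(config$panel_path)) {
    panel <- read_panel(config$panel_path)
  } else panel <- NULL
  meta <- generate_cohort(config$n_per_group, config$n_female_per_group,
                          config$age_range, config$n_batches,
                          seed = substream_seed(seed, "cohort"))
  tables <- generate_tables(
    meta, config$n_cell_mets, config$n_media_mets, config$n_shared,
    batch_sd = config$batch_sd, noise_sd = config$noise_sd,
    sample_sd = config$sample_sd, censor_fraction = config$censor_fraction,
    effects = config$effects, ratio_effects = config$ratio_effects,
    seed = substream_seed(seed, "tables"))
  if (is.null(panel)) panel <- synthetic_panel(tables, config$panel_size)
  matching <- verify_matching(meta)

  files <- character()
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  emit(write_metadata, meta, "metadata.tsv")
  emit(write_abundance_table, tables$cells, "raw_cells.tsv")
  emit(write_abundance_table, tables$media, "raw_media.tsv")
  emit(write_abundance_table, tables$blank, "raw_blank.tsv")
  emit(write_panel, panel, "panel.txt")

  # --- normalize (one pass per matrix, shared by all arms) ----------------
  norm <- list(cells = normalize_matrix(tables$cells),
               media = normalize_matrix(tables$media),
               blank = normalize_matrix(tables$blank))

  # --- analysis arms ------------------------------------------------------
  # Moderated tests run on the natural-log scale (the per-feature t is
  # scale invariant, and variance pooling is only calibrated there);
  # center-scaled values feed clustering and classification.
  ratio_cm <- cell_media_ratios(norm$cells, norm$media)
  metabo <- pairwise_panel_ratios(norm$media, panel)
  arms <- list(
    cells = c(list(values = norm$cells$scaled_values),
              sig_sets(norm$cells$log_values, meta, alpha,
                       colnames(norm$cells$scaled_values))),
    media = c(list(values = norm$media$scaled_values),
              sig_sets(norm$media$log_values, meta, alpha,
                       colnames(norm$media$scaled_values))),
    cell_media_ratio = c(list(values = ratio_cm$scaled),
                         sig_sets(ratio_cm$values, meta, alpha,
                                  colnames(ratio_cm$scaled))),
    metabotype_ratio = c(list(values = metabo$scaled),
                         sig_sets(metabo$values, meta, alpha,
                                  colnames(metabo$scaled))))
  for (arm in names(arms)) {
    for (grouping in c("two_group", "three_group")) {
      emit(write_diff_results, arms[[arm]]$diff[[grouping]],
           sprintf("diff_%s_%s.tsv", arm, grouping))
    }
  }

  # --- correlation blocks and sample clustering on each arm's features ----
  corr <- NULL; blocks <- NULL
  sig_metabo <- arms$metabotype_ratio$significant$two_group
  two_ids <- meta$sample_id[meta$group %in% GROUP_LEVELS[1:2]]
  if (length(sig_metabo) >= 3L) {
    corr <- correlation_matrix(metabo$scaled[two_ids, sig_metabo, drop = FALSE])
    blocks <- detect_negative_blocks(corr)
    bl <- blocks
    attr(bl, "members") <- NULL; attr(bl, "order") <- NULL
    emit(function(obj, path) utils::write.table(
      obj, path, sep = "\t", quote = FALSE, row.names = FALSE),
      bl, "metabotype_negative_blocks.tsv")
  }
  clusters <- list(); miscl <- list()
  labels <- stats::setNames(as.character(meta$group), meta$sample_id)
  for (arm in names(arms)) {
    sig <- arms[[arm]]$significant$two_group
    if (length(sig) >= 2L) {
      cl <- hcluster_samples(arms[[arm]]$values[two_ids, sig, drop = FALSE],
                             labels[two_ids])
      clusters[[arm]] <- cl
      miscl[[arm]] <- misclassified_samples(cl, k = 2L)
      emit(function(obj, path) writeLines(obj, path),
           c("# leaf order (complete linkage, correlation distance)",
             cl$leaf_order,
             "# misclassified at k = 2",
             if (length(miscl[[arm]])) miscl[[arm]] else "(none)"),
           sprintf("cluster_%s.txt", arm))
    }
  }

  # --- classification performance grid ------------------------------------
  perf <- performance_grid(arms, meta, config)
  grid_out <- perf$grid
  for (cl in c("accuracy", "ci_low", "ci_high", "nir", "p_vs_nir",
               "sensitivity", "specificity"))
    grid_out[[cl]] <- fmt_num(grid_out[[cl]])
  emit(function(obj, path) utils::write.table(
    obj, path, sep = "\t", quote = FALSE, row.names = FALSE),
    grid_out, "performance_grid.tsv")

  manifest <- write_manifest(
    out_dir, config, files,
    extra = c(fisher_sex_p = fmt_num(matching$fisher_p),
              kruskal_age_p = fmt_num(matching$kruskal_p),
              metabotype_detected_media = as.character(metabo$n_detected),
              shared_metabolites = as.character(ratio_cm$n_detected)))

  invisible(list(meta = meta, tables = tables, panel = panel, norm = norm,
                 arms = arms, matching = matching, corr = corr,
                 blocks = blocks, clusters = clusters,
                 misclassified = miscl, performance = perf,
                 files = c(files, manifest), out_dir = out_dir))
}
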