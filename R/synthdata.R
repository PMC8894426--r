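#' Generate a matched synthetic cohort
#'
#' Emulates the study design: three phenotype groups of equal size with
#' identical sex composition, ages drawn from the same law in every group
#' (so the groups are exchangeable in age), and instrument batches
#' assigned round-robin within group so batch is never confounded with
#' phenotype.
#'
#' @param n_per_group samples per phenotype group.
#' @param n_female_per_group females per group (the remainder are male).
#' @param age_range numeric length-2, `(low, high)` years; ages are drawn
#'   uniformly over this range.
#' @param n_batches number of instrument batches.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated metadata data.frame (see [validate_metadata()]).
#' @examples
#' meta <- generate_cohort(10, 7, c(2, 59), n_batches = 2, seed = 1)
#' table(meta$group, meta$sex)
#' @export
generate_cohort <- function(n_per_group = 10L, n_female_per_group = 7L,
                            age_range = c(2, 59), n_batches = 2L, seed = 1L) {
  if (n_per_group < 1L)
    stop("`n_per_group` must be a positive integer")
  if (n_female_per_group < 0L || n_female_per_group > n_per_group)
    stop("`n_female_per_group` must lie in [0, n_per_group]")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("`age_range` must be (low, high) with low < high")
  if (n_batches < 1L)
    stop("`n_batches` must be a positive integer")
  with_seed(seed, {
    rows <- lapply(seq_along(GROUP_LEVELS), function(g) {
      grp <- GROUP_LEVELS[g]
      data.frame(
        sample_id = sprintf("%s_%02d", grp, seq_len(n_per_group)),
        group = grp,
        sex = c(rep("F", n_female_per_group),
                rep("M", n_per_group - n_female_per_group)),
        age_at_consent = stats::runif(n_per_group, age_range[1], age_range[2]),
        batch = ((seq_len(n_per_group) - 1L) %% n_batches) + 1L,
        stringsAsFactors = FALSE)
    })
    validate_metadata(do.call(rbind, rows))
  })
}

#' Check sex and age matching of a cohort
#'
#' Fisher's exact test on the group-by-sex contingency table and the
#' Kruskal-Wallis rank sum test on age at consent, the two checks used to
#' certify a matched design.
#'
#' @param meta cohort metadata.
#' @return list with `fisher_p` and `kruskal_p`.
#' @export
verify_matching <- function(meta) {
  meta <- validate_metadata(meta)
  groups <- droplevels(meta$group)
  if (nlevels(groups) < 2L)
    stop("matching checks need at least two groups")
  if (any(table(groups) < 2L))
    stop("matching checks need at least two samples per group")
  tab <- table(groups, meta$sex)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  fisher_p <- if (ncol(tab) < 2L) 1 else stats::fisher.test(tab)$p.value
  kruskal_p <- stats::kruskal.test(meta$age_at_consent, groups)$p.value
  list(fisher_p = fisher_p, kruskal_p = kruskal_p)
}

# Draw one matrix of log-scale abundances:
# log x = baseline(metabolite) + batch factor(metabolite, batch)
#         + sample factor(sample) + planted group effect + noise.
simulate_log_matrix <- function(meta, met_ids, baseline, batch_sd, noise_sd,
                                sample_shift, effects = NULL) {
  n <- nrow(meta); p <- length(met_ids)
  batches <- sort(unique(meta$batch))
  bf <- matrix(stats::rnorm(length(batches) * p, 0, batch_sd),
               nrow = length(batches), dimnames = list(batches, met_ids))
  logx <- matrix(baseline, nrow = n, ncol = p, byrow = TRUE,
                 dimnames = list(meta$sample_id, met_ids))
  logx <- logx + bf[as.character(meta$batch), , drop = FALSE] + sample_shift
  if (!is.null(effects) && nrow(effects)) {
    for (k in seq_len(nrow(effects))) {
      idx <- meta$group == effects$group[k]
      logx[idx, effects$metabolite_id[k]] <-
        logx[idx, effects$metabolite_id[k]] + effects$log_effect[k]
    }
  }
  logx + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
}

# Left-censor values below the per-metabolite censor_fraction quantile.
censor_matrix <- function(x, censor_fraction) {
  if (censor_fraction <= 0) return(x)
  for (j in seq_len(ncol(x))) {
    thr <- stats::quantile(x[, j], censor_fraction, names = FALSE)
    below <- x[, j] < thr
    # never censor everything: keep at least one observed value
    if (sum(!below) == 0L) below[which.max(x[, j])] <- FALSE
    x[below, j] <- NA_real_
  }
  x
}

#' Generate synthetic two-matrix abundance tables
#'
#' Draws raw peak-area tables for cells, spent media and blank media with
#' the statistical structure the downstream analysis assumes:
#' log-normal per-metabolite baselines, multiplicative per-(metabolite,
#' batch) instrument effects, optional per-sample loading factors shared
#' between a sample's cells and media measurements, independent
#' log-normal observation noise, planted group effects, and left
#' censoring at a per-metabolite detection-limit quantile. A ground-truth
#' record of every planted effect is returned for recovery testing.
#'
#' @param meta cohort metadata from [generate_cohort()].
#' @param n_cell_mets,n_media_mets metabolites measured per matrix.
#' @param n_shared metabolites detected in both matrices
#'   (`n_shared <= min(n_cell_mets, n_media_mets)`).
#' @param batch_sd log-scale SD of the per-(metabolite, batch)
#'   multiplicative instrument effect.
#' @param noise_sd log-scale SD of independent observation noise.
#' @param sample_sd log-scale SD of the per-sample loading factor, shared
#'   between the cells and media measurement of a sample. The default 0
#'   generates independent samples; positive values emulate the paired
#'   technical variation that ratio features cancel.
#' @param censor_fraction fraction in `[0, 1)` of each metabolite's values
#'   set missing (left-censored at that empirical quantile).
#' @param effects optional data.frame of planted single-metabolite group
#'   effects: columns `metabolite_id`, `matrix` (`"cells"`/`"media"`),
#'   `group`, `log_effect`.
#' @param ratio_effects optional data.frame of planted coordinated pair
#'   effects: columns `met_a`, `met_b`, `matrix`, `group`, `log_effect`
#'   (the pair's log-ratio shift; each member moves by half in opposite
#'   directions, see [plant_ratio_effects()]).
#' @param n_blank number of blank (unconditioned) media aliquots.
#' @param seed integer seed.
#' @return list with `cells`, `media`, `blank` ([abundance_table]s) and
#'   `truth` (a `synthetic_truth` record of planted effects and
#'   generator settings).
#' @export
generate_tables <- function(meta, n_cell_mets = 645L, n_media_mets = 489L,
                            n_shared = 386L, batch_sd = 0.3, noise_sd = 0.3,
                            sample_sd = 0, censor_fraction = 0.05,
                            effects = NULL, ratio_effects = NULL,
                            n_blank = 3L, seed = 1L) {
  meta <- validate_metadata(meta)
  if (n_shared > min(n_cell_mets, n_media_mets))
    stop("`n_shared` cannot exceed the smaller matrix's metabolite count")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("`censor_fraction` must lie in [0, 1)")
  shared_ids <- sprintf("met_s%04d", seq_len(n_shared))
  cell_ids <- c(shared_ids, sprintf("met_c%04d", seq_len(n_cell_mets - n_shared)))
  media_ids <- c(shared_ids, sprintf("met_m%04d", seq_len(n_media_mets - n_shared)))

  eff_for <- function(eff, mat) {
    if (is.null(eff) || !nrow(eff)) return(NULL)
    eff[eff$matrix == mat, , drop = FALSE]
  }
  if (!is.null(effects)) {
    stopifnot(all(c("metabolite_id", "matrix", "group", "log_effect") %in% names(effects)))
    ok <- ifelse(effects$matrix == "cells", effects$metabolite_id %in% cell_ids,
                 effects$metabolite_id %in% media_ids)
    if (!all(ok))
      stop("planted effect names metabolite absent from its matrix")
  }

  out <- with_seed(seed, {
    n <- nrow(meta)
    # baseline log-abundances: positive right-skewed peak areas
    base_cells <- stats::rnorm(n_cell_mets, 10, 2)
    base_media <- stats::rnorm(n_media_mets, 10, 2)
    base_blank <- stats::rnorm(n_media_mets, 10, 2)
    # per-sample loading factor, shared between the two matrices
    shift <- stats::rnorm(n, 0, sample_sd)
    log_cells <- simulate_log_matrix(meta, cell_ids, base_cells, batch_sd,
                                     noise_sd, shift, eff_for(effects, "cells"))
    log_media <- simulate_log_matrix(meta, media_ids, base_media, batch_sd,
                                     noise_sd, shift, eff_for(effects, "media"))
    blank_meta <- data.frame(
      sample_id = sprintf("BLANK_%02d", seq_len(n_blank)),
      group = GROUP_LEVELS[1], sex = "F", age_at_consent = 1,
      batch = ((seq_len(n_blank) - 1L) %% max(meta$batch)) + 1L)
    log_blank <- simulate_log_matrix(blank_meta, media_ids, base_blank,
                                     batch_sd, noise_sd,
                                     stats::rnorm(n_blank, 0, sample_sd))
    # 20% CV log-normal protein concentration, mean 1; raw cell-pellet
    # peak areas scale with the protein content (protein normalization
    # is what removes it again)
    sdlog <- sqrt(log(1 + 0.2^2))
    protein <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    log_cells <- log_cells + log(protein)
    list(log_cells = log_cells, log_media = log_media, log_blank = log_blank,
         blank_batch = blank_meta$batch, protein = protein)
  })

  cells <- abundance_table(censor_matrix(exp(out$log_cells), censor_fraction),
                           "cells", meta$batch, out$protein)
  media <- abundance_table(censor_matrix(exp(out$log_media), censor_fraction),
                           "media", meta$batch)
  blank <- abundance_table(exp(out$log_blank), "blank", out$blank_batch)

  tables <- list(cells = cells, media = media, blank = blank)
  if (!is.null(ratio_effects) && nrow(ratio_effects)) {
    stopifnot(all(c("met_a", "met_b", "matrix", "group", "log_effect") %in%
                    names(ratio_effects)))
    for (k in seq_len(nrow(ratio_effects))) {
      re <- ratio_effects[k, ]
      tables[[re$matrix]] <- plant_ratio_effects(
        tables[[re$matrix]], meta,
        pairs = data.frame(met_a = re$met_a, met_b = re$met_b),
        effect = re$log_effect, group = re$group)
    }
  }

  truth <- structure(list(
    effects = effects, ratio_effects = ratio_effects, seed = seed,
    censor_fraction = censor_fraction, batch_sd = batch_sd,
    noise_sd = noise_sd, sample_sd = sample_sd,
    shared_ids = shared_ids), class = "synthetic_truth")
  c(tables, list(truth = truth))
}

#' Plant a coordinated pair (ratio) effect into an abundance table
#'
#' For each pair `(A, B)` the listed group's samples get `A` multiplied by
#' `exp(+effect/2)` and `B` by `exp(-effect/2)`: the pair's log ratio
#' shifts by `effect` while the per-metabolite shift is only half of it
#' and the per-sample mean of `log A + log B` is unchanged. This is the
#' kind of alteration a pairwise ratio analysis can capture that
#' single-metabolite analysis struggles with.
#'
#' @param table an [abundance_table].
#' @param meta cohort metadata covering the table's samples.
#' @param pairs data.frame with columns `met_a`, `met_b`.
#' @param effect log-ratio shift.
#' @param group group label receiving the shift.
#' @return the modified [abundance_table].
#' @export
plant_ratio_effects <- function(table, meta, pairs, effect, group) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- validate_metadata(meta)
  miss <- setdiff(unique(c(pairs$met_a, pairs$met_b)), colnames(table$values))
  if (length(miss))
    stop(sprintf("unknown metabolite(s) in ratio pairs: %s",
                 paste(miss, collapse = ", ")))
  if (!group %in% GROUP_LEVELS)
    stop(sprintf("unknown group %s", group))
  idx <- rownames(table$values) %in% meta$sample_id[meta$group == group]
  for (k in seq_len(nrow(pairs))) {
    table$values[idx, pairs$met_a[k]] <-
      table$values[idx, pairs$met_a[k]] * exp(effect / 2)
    table$values[idx, pairs$met_b[k]] <-
      table$values[idx, pairs$met_b[k]] * exp(-effect / 2)
  }
  table
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> seed %d, %d single effect(s), %d ratio pair(s), censor %.2f\n",
              x$seed, if (is.null(x$effects)) 0L else nrow(x$effects),
              if (is.null(x$ratio_effects)) 0L else nrow(x$ratio_effects),
              x$censor_fraction))
  invisible(x)
}
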