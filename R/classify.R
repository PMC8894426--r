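# LOOCV LogitBoost classification of phenotype groups from significant
# features, with three feature-extraction variants and confusion-matrix
# reporting against the no-information rate.

#' Remove linearly dependent and highly correlated features
#'
#' Two passes. First, exact linear combinations are found by a
#' rank-revealing pivoted QR decomposition (tolerance 1e-8 on the
#' diagonal ratios of R) and the non-pivot columns removed. Second,
#' greedy pairwise pruning: while any pair of remaining features has
#' |correlation| at or above `threshold`, the pair with the largest
#' |correlation| is visited (ties by column order) and the member with
#' the larger mean absolute correlation to everything else is dropped
#' (ties drop the later column). Deterministic by construction.
#'
#' @param X samples x features matrix.
#' @param threshold pairwise |correlation| threshold (default 0.90).
#' @return the pruned matrix, with a `removed` attribute.
#' @export
remove_linear_correlated <- function(X, threshold = 0.90) {
  if (ncol(X) < 2L) return(X)
  removed <- character()
  # constant columns carry no information and break correlations
  sdv <- apply(X, 2L, stats::sd)
  removed <- c(removed, colnames(X)[sdv == 0])
  X <- X[, sdv > 0, drop = FALSE]
  if (ncol(X) >= 2L) {
    qrX <- qr(X, tol = 1e-8)
    if (qrX$rank < ncol(X)) {
      drop_idx <- qrX$pivot[seq(qrX$rank + 1L, ncol(X))]
      removed <- c(removed, colnames(X)[drop_idx])
      X <- X[, -drop_idx, drop = FALSE]
    }
  }
  while (ncol(X) >= 2L) {
    r <- stats::cor(X)
    diag(r) <- 0
    mx <- max(abs(r))
    if (mx < threshold) break
    hit <- which(abs(r) == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    mean_abs <- rowMeans(abs(r))
    drop_j <- if (mean_abs[hit[1]] > mean_abs[hit[2]]) hit[1] else hit[2]
    removed <- c(removed, colnames(X)[drop_j])
    X <- X[, -drop_j, drop = FALSE]
  }
  attr(X, "removed") <- removed
  X
}

#' PCA dimension reduction by explained-variance threshold
#'
#' Centers the features, computes principal components, and keeps the
#' smallest number of components whose cumulative explained variance
#' reaches `variance_threshold`.
#'
#' @param X samples x features matrix.
#' @param variance_threshold cumulative explained-variance target in
#'   `(0, 1]`.
#' @return scores matrix (samples x k) with attributes `k`, `rotation`,
#'   `center` for projecting new samples.
#' @export
pca_reduce <- function(X, variance_threshold = 0.95) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("`variance_threshold` must lie in (0, 1]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_threshold - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "k") <- k
  attr(scores, "rotation") <- pc$rotation[, seq_len(k), drop = FALSE]
  attr(scores, "center") <- pc$center
  scores
}

# Weighted least-squares decision stump over all (feature, threshold)
# midpoint candidates. ord: per-feature sort orders (precomputed).
# Ties in loss broken by (feature index, threshold) order.
fit_stump <- function(X, z, w, ord) {
  n <- nrow(X)
  TW <- sum(w); TWZ <- sum(w * z)
  best <- list(sse = Inf, feature = NA_integer_, threshold = Inf,
               left = TWZ / TW, right = TWZ / TW)
  for (j in seq_len(ncol(X))) {
    o <- ord[[j]]
    xs <- X[o, j]
    valid <- which(diff(xs) > 0)
    if (!length(valid)) next
    ws <- w[o]; zs <- z[o]
    SW <- cumsum(ws); SWZ <- cumsum(ws * zs)
    lw <- SW[valid]; lz <- SWZ[valid]
    rw <- TW - lw; rz <- TWZ - lz
    sse <- -(lz^2 / lw + rz^2 / rw)  # additive constant dropped
    k <- valid[which.min(sse)]
    s <- min(sse)
    if (s < best$sse - 1e-12) {
      best <- list(sse = s, feature = j,
                   threshold = (xs[k] + xs[k + 1]) / 2,
                   left = SWZ[k] / SW[k],
                   right = (TWZ - SWZ[k]) / (TW - SW[k]))
    }
  }
  best
}

# One binary LogitBoost committee (Friedman/Hastie/Tibshirani additive
# logistic regression with stumps). ybin in {0,1}.
boost_binary <- function(X, ybin, n_iter) {
  n <- nrow(X)
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  Fv <- numeric(n); p <- rep(0.5, n)
  stumps <- vector("list", n_iter)
  for (m in seq_len(n_iter)) {
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    w <- p * (1 - p)
    z <- (ybin - p) / w
    st <- fit_stump(X, z, w, ord)
    fm <- ifelse(is.na(st$feature) | X[, max(st$feature, 1L)] <= st$threshold,
                 st$left, st$right)
    Fv <- Fv + 0.5 * fm
    p <- 1 / (1 + exp(-2 * Fv))
    stumps[[m]] <- st[c("feature", "threshold", "left", "right")]
  }
  stumps
}

committee_scores <- function(stumps, X, n_iter = length(stumps)) {
  Fv <- numeric(nrow(X))
  out <- matrix(NA_real_, nrow(X), n_iter)
  for (m in seq_len(n_iter)) {
    st <- stumps[[m]]
    fm <- if (is.na(st$feature)) rep(st$left, nrow(X)) else
      ifelse(X[, st$feature] <= st$threshold, st$left, st$right)
    Fv <- Fv + 0.5 * fm
    out[, m] <- Fv
  }
  out
}

#' Fit a LogitBoost stump ensemble
#'
#' Additive logistic boosting with decision stumps: each iteration fits
#' a weighted least-squares stump to the working response
#' `z = (y* - p) / (p (1 - p))` with weights `w = p (1 - p)`
#' (probabilities clipped to `[1e-4, 1 - 1e-4]`), adds half its fitted
#' value to the committee, and updates probabilities through the
#' logistic link. Multiclass problems fit one one-vs-rest committee per
#' class.
#'
#' @param X samples x features matrix.
#' @param y factor (or character) class labels, at least two classes.
#' @param n_iter boosting iterations.
#' @return a `logitboost` model.
#' @export
fit_logitboost <- function(X, y, n_iter = 31L) {
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least two classes in `y`")
  if (n_iter < 1L) stop("`n_iter` must be >= 1")
  X <- as.matrix(X)
  committees <- if (nlevels(y) == 2L) {
    list(boost_binary(X, as.integer(y == levels(y)[2]), n_iter))
  } else {
    lapply(levels(y), function(lv)
      boost_binary(X, as.integer(y == lv), n_iter))
  }
  structure(list(committees = committees, levels = levels(y),
                 n_iter = n_iter, binary = nlevels(y) == 2L),
            class = "logitboost")
}

#' Predict from a LogitBoost model
#'
#' @param object a `logitboost` model.
#' @param newdata samples x features matrix.
#' @param n_iter use only the first `n_iter` iterations (default: all).
#' @param type `"class"` or `"score"` (committee score(s)).
#' @param ... unused.
#' @export
predict.logitboost <- function(object, newdata, n_iter = object$n_iter,
                               type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  sc <- vapply(object$committees, function(comm)
    committee_scores(comm, newdata, n_iter)[, n_iter],
    numeric(nrow(newdata)))
  sc <- matrix(sc, nrow = nrow(newdata))
  if (type == "score") return(sc)
  if (object$binary) {
    factor(ifelse(sc[, 1] > 0, object$levels[2], object$levels[1]),
           levels = object$levels)
  } else {
    factor(object$levels[max.col(sc, ties.method = "first")],
           levels = object$levels)
  }
}

# Apply a feature-extraction variant, returning the transformed matrix
# and a projector for new samples.
apply_variant <- function(X, variant, variance_threshold, corr_threshold) {
  switch(variant,
    ALL_SIG = list(train = X, project = function(new) new,
                   n_features = ncol(X)),
    REMOVE_LINEAR_CORRELATED = {
      Xr <- remove_linear_correlated(X, corr_threshold)
      keep <- colnames(Xr)
      list(train = Xr, project = function(new) new[, keep, drop = FALSE],
           n_features = ncol(Xr))
    },
    PCA = {
      sc <- pca_reduce(X, variance_threshold)
      rot <- attr(sc, "rotation"); ctr <- attr(sc, "center")
      list(train = sc,
           project = function(new)
             sweep(new, 2L, ctr, "-") %*% rot,
           n_features = attr(sc, "k"))
    },
    stop(sprintf("unknown variant: %s", variant)))
}

#' Leave-one-out cross-validation with LogitBoost
#'
#' Each sample is predicted by a committee fitted on the other `n - 1`
#' samples. The iteration count is chosen from `iter_grid` by highest
#' LOOCV accuracy (ties take the smallest count). In the default
#' "paper" mode the feature-extraction variant is fitted once on all
#' samples before cross-validation, mirroring the original study's
#' procedure (an optimistic bias, reported as such); `nested = TRUE`
#' refits the variant inside every fold.
#'
#' @param X samples x features matrix of significant features.
#' @param y class labels.
#' @param variant `"ALL_SIG"`, `"REMOVE_LINEAR_CORRELATED"` or `"PCA"`.
#' @param iter_grid candidate boosting iteration counts.
#' @param nested refit feature extraction within each fold?
#' @param variance_threshold,corr_threshold variant parameters.
#' @return list with `predictions` (factor, one per sample), `truth`,
#'   `n_iter` (selected), `grid_accuracy`, `n_features`, `nested`.
#' @export
loocv <- function(X, y, variant = "ALL_SIG", iter_grid = c(11L, 21L, 31L),
                  nested = FALSE, variance_threshold = 0.95,
                  corr_threshold = 0.90) {
  y <- droplevels(factor(y))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  iter_grid <- sort(unique(as.integer(iter_grid)))
  max_iter <- max(iter_grid)
  n_features <- ncol(X)
  if (!nested) {
    tv <- apply_variant(X, variant, variance_threshold, corr_threshold)
    Xt <- tv$train
    n_features <- tv$n_features
  }
  pred_grid <- matrix(NA_character_, n, length(iter_grid))
  for (i in seq_len(n)) {
    if (nested) {
      tv <- apply_variant(X[-i, , drop = FALSE], variant,
                          variance_threshold, corr_threshold)
      Xtr <- tv$train
      Xte <- tv$project(X[i, , drop = FALSE])
      n_features <- tv$n_features
    } else {
      Xtr <- Xt[-i, , drop = FALSE]
      Xte <- Xt[i, , drop = FALSE]
    }
    fit <- fit_logitboost(Xtr, y[-i], n_iter = max_iter)
    for (g in seq_along(iter_grid)) {
      pred_grid[i, g] <-
        as.character(predict(fit, Xte, n_iter = iter_grid[g]))
    }
  }
  acc <- colMeans(pred_grid == as.character(y))
  best <- which.max(acc)  # ties -> first, i.e. smallest n_iter
  list(predictions = factor(pred_grid[, best], levels = levels(y)),
       truth = y, n_iter = iter_grid[best],
       grid_accuracy = stats::setNames(acc, iter_grid),
       n_features = n_features, nested = nested)
}

#' Confusion-matrix report with exact intervals and NIR comparison
#'
#' Builds the truth x prediction confusion matrix and reports overall
#' accuracy with its exact 95% Clopper-Pearson interval, the
#' no-information rate (largest class frequency), the one-sided exact
#' binomial p-value of accuracy against the NIR, and sensitivity /
#' specificity for the declared positive class (per-class one-vs-rest
#' for more than two classes).
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param positive_class positive class for sensitivity/specificity.
#' @return a `classification_report`.
#' @export
confusion_report <- function(pred, truth, positive_class = "CANCER") {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have the same length")
  # class set = every level observed in either vector (a prediction into a
  # class missing from the truth must still count as an error)
  lev_all <- union(levels(factor(truth)), levels(factor(pred)))
  seen <- union(as.character(truth), as.character(pred))
  lev <- lev_all[lev_all %in% seen]
  truth <- factor(as.character(truth), levels = lev)
  pred <- factor(as.character(pred), levels = lev)
  cm <- table(truth = truth, predicted = pred)
  n <- sum(cm)
  correct <- sum(diag(cm))
  acc <- correct / n
  ci <- stats::binom.test(correct, n)$conf.int  # exact Clopper-Pearson
  nir <- max(rowSums(cm)) / n
  p_vs_nir <- stats::pbinom(correct - 1L, n, nir, lower.tail = FALSE)
  lev <- levels(truth)
  sens_spec <- function(lv) {
    tp <- cm[lv, lv]
    fn <- sum(cm[lv, ]) - tp
    fp <- sum(cm[, lv]) - tp
    tn <- n - tp - fn - fp
    c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  }
  if (length(lev) == 2L) {
    if (!positive_class %in% lev)
      stop(sprintf("positive class %s absent from labels", positive_class))
    ss <- sens_spec(positive_class)
    sens <- ss["sensitivity"]; spec <- ss["specificity"]
  } else {
    ss <- vapply(lev, sens_spec, numeric(2))
    sens <- stats::setNames(ss["sensitivity", ], lev)
    spec <- stats::setNames(ss["specificity", ], lev)
  }
  structure(list(confusion = cm, overall_accuracy = acc,
                 ci95 = c(ci[1], ci[2]), nir = nir, p_vs_nir = p_vs_nir,
                 sensitivity = unname(sens)[if (length(lev) == 2L) 1 else seq_along(lev)],
                 specificity = unname(spec)[if (length(lev) == 2L) 1 else seq_along(lev)],
                 positive_class = if (length(lev) == 2L) positive_class else NA_character_,
                 class_levels = lev, n = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n = %d\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.3f (95%% CI %.3f-%.3f), NIR %.3f, p vs NIR %.3g\n",
              x$overall_accuracy, x$ci95[1], x$ci95[2], x$nir, x$p_vs_nir))
  if (!is.na(x$positive_class))
    cat(sprintf("positive class %s: sensitivity %.3f, specificity %.3f\n",
                x$positive_class, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classification performance grid
#'
#' One LOOCV LogitBoost evaluation per combination of feature source
#' (cells, media, cells/media ratios, metabotype ratios), extraction
#' variant (all significant features, linear-correlation removal, PCA)
#' and grouping (two-group ASD/DD vs cancer, or all three groups). Rows
#' with an empty significant-feature set are emitted with `n_features =
#' 0` and `NA` metrics.
#'
#' @param feature_sets named list (per source matrix) of lists with
#'   elements `values` (samples x features, scaled) and `significant`
#'   (named by grouping: character vectors of significant feature ids).
#' @param meta cohort metadata.
#' @param config pipeline config (see [load_config()]).
#' @return list with `grid` (data.frame mirroring the performance table)
#'   and `reports` (the full `classification_report` per row).
#' @export
performance_grid <- function(feature_sets, meta, config = load_config()) {
  meta <- validate_metadata(meta)
  variants <- c("ALL_SIG", "REMOVE_LINEAR_CORRELATED", "PCA")
  groupings <- c("two_group", "three_group")
  rows <- list(); reports <- list()
  for (src in names(feature_sets)) {
    fs <- feature_sets[[src]]
    for (grouping in groupings) {
      sig <- fs$significant[[grouping]]
      if (grouping == "two_group") {
        keep <- meta$group %in% GROUP_LEVELS[1:2]
      } else keep <- rep(TRUE, nrow(meta))
      ids <- meta$sample_id[keep]
      y <- droplevels(meta$group[keep])
      for (variant in variants) {
        key <- sprintf("%s.%s.%s", src, grouping, variant)
        if (is.null(sig) || !length(sig)) {
          rows[[key]] <- data.frame(
            source = src, grouping = grouping, variant = variant,
            n_features = 0L, n_iter = NA_integer_, accuracy = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, nir = NA_real_,
            p_vs_nir = NA_real_, sensitivity = NA_real_,
            specificity = NA_real_, stringsAsFactors = FALSE)
          next
        }
        Xs <- fs$values[ids, sig, drop = FALSE]
        cv <- loocv(Xs, y, variant = variant,
                    iter_grid = config$logitboost_iter_grid,
                    variance_threshold = config$pca_variance_threshold,
                    corr_threshold = config$corr_removal_threshold)
        rep_ <- confusion_report(cv$predictions, y,
                                 positive_class = config$positive_class)
        reports[[key]] <- rep_
        rows[[key]] <- data.frame(
          source = src, grouping = grouping, variant = variant,
          n_features = cv$n_features, n_iter = cv$n_iter,
          accuracy = rep_$overall_accuracy,
          ci_low = rep_$ci95[1], ci_high = rep_$ci95[2],
          nir = rep_$nir, p_vs_nir = rep_$p_vs_nir,
          sensitivity = rep_$sensitivity[1],
          specificity = rep_$specificity[1], stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  list(grid = grid, reports = reports)
}
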