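# Covariate-adjusted differential abundance: per-feature least squares
# with age and sex covariates, empirical-Bayes variance moderation via
# closed-form moment matching on log variances, BH correction, and the
# classical pairwise two-sample tests.

#' Build a covariate-adjusted design matrix
#'
#' Two-group contrasts yield intercept + group indicator + age + sex on
#' the samples belonging to the contrast; `"three_group"` yields two
#' group indicators + age + sex on all samples.
#'
#' @param meta cohort metadata.
#' @param contrast either `c(groupA, groupB)` or `"three_group"`.
#' @return a design matrix with a `samples` attribute (the retained
#'   sample ids, in metadata order) and a `test_cols` attribute naming
#'   the group-effect column(s).
#' @export
build_design <- function(meta, contrast) {
  meta <- validate_metadata(meta)
  if (identical(contrast, "three_group")) {
    sel <- meta
    test_cols <- paste0("group", GROUP_LEVELS[2:3])
  } else {
    if (length(contrast) != 2L || !all(contrast %in% GROUP_LEVELS))
      stop(sprintf("contrast must be 'three_group' or two of %s",
                   paste(GROUP_LEVELS, collapse = ", ")))
    sel <- meta[meta$group %in% contrast, , drop = FALSE]
    sel$group <- factor(as.character(sel$group), levels = contrast)
    test_cols <- paste0("group", contrast[2])
  }
  if (!nrow(sel)) stop("no samples in the requested contrast")
  if (length(unique(sel$sex)) < 2L)
    stop("design matrix is rank deficient (constant column: sexM); consider dropping that covariate")
  if (length(unique(sel$age_at_consent)) < 2L)
    stop("design matrix is rank deficient (constant column: age_at_consent); consider dropping that covariate")
  X <- stats::model.matrix(~ group + age_at_consent + sex,
                           data = droplevels(sel))
  colnames(X)[colnames(X) == "sexM"] <- "sexM"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    const <- names(which(apply(X[, -1, drop = FALSE], 2L,
                               function(cl) length(unique(cl)) == 1L)))
    stop(sprintf("design matrix is rank deficient%s; consider dropping that covariate",
                 if (length(const)) sprintf(" (constant column: %s)",
                                            paste(const, collapse = ", ")) else ""))
  }
  attr(X, "samples") <- sel$sample_id
  attr(X, "test_cols") <- test_cols
  X
}

#' Per-feature ordinary least squares
#'
#' Fits the same design to every feature by QR decomposition and returns
#' the per-feature coefficients, residual variances and (common) residual
#' degrees of freedom.
#'
#' @param Y numeric matrix, samples x features, rows aligned with `X`.
#' @param X design matrix from [build_design()].
#' @return list with `beta` (coefficients x features), `s2` (residual
#'   variances), `df_residual`, `XtX_inv_diag`, and the design.
#' @export
fit_linear_models <- function(Y, X) {
  if (nrow(Y) != nrow(X)) stop("Y rows must align with the design matrix")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more samples than design columns")
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is numerically singular")
  beta <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  s2 <- colSums(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  list(beta = beta, s2 = s2, df_residual = n - p,
       XtX_inv = XtX_inv, design = X)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` by monotone Newton iteration (tolerance
#' 1e-10, at most 100 iterations), the building block of the moment
#' estimator for the prior degrees of freedom.
#'
#' @param x positive value(s).
#' @return y with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in seq_len(100L)) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) return(y)
    }
    stop(sprintf("trigamma inversion did not converge (x = %g, last y = %g)", xi, y))
  }, numeric(1))
}

#' Fit the variance-moderation prior
#'
#' Moment matching on log residual variances: with `e = log(s2) -
#' digamma(d/2) + log(d/2)`, the excess of `var(e)` over `trigamma(d/2)`
#' identifies the prior degrees of freedom `d0` through the trigamma
#' function, and the first moment then gives the prior variance `s0^2`.
#' When the observed log variances are no more dispersed than a
#' chi-square implies, `d0` is infinite and `s0^2` is the (bias
#' corrected) geometric-mean pooled variance.
#'
#' @param s2 per-feature residual variances (zero-variance features must
#'   be excluded by the caller).
#' @param df residual degrees of freedom of each `s2`.
#' @return list with `d0` (possibly `Inf`) and `s0_sq`, class
#'   `moderation_prior`.
#' @export
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10L)
    stop("need at least 10 positive residual variances to fit the prior")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat(sprintf("<moderation_prior> d0 = %s, s0^2 = %.6g\n",
              if (is.finite(x$d0)) sprintf("%.4g", x$d0) else "Inf", x$s0_sq))
  invisible(x)
}

#' Moderated t (or F) test per feature
#'
#' Shrinks each feature's residual variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and tests the group
#' coefficient with a Student t on `d0 + d_g` degrees of freedom (normal
#' reference when `d0` is infinite and the total exceeds 200). With two
#' group columns (three-group design) a moderated omnibus F on the group
#' coefficients is used instead.
#'
#' @param fits output of [fit_linear_models()].
#' @param prior a `moderation_prior`; defaults to fitting it from `fits`.
#' @param alpha adjusted-significance threshold.
#' @return a `diff_result` data.frame: `feature`, `coef`, `se`,
#'   `t_ordinary`, `t_moderated`, `df_residual`, `df_total`, `p_raw`,
#'   `p_adj`, `significant` (and `F_*` analogues for omnibus tests).
#' @export
moderated_test <- function(fits, prior = NULL, alpha = 0.05) {
  X <- fits$design
  test_cols <- attr(X, "test_cols")
  s2 <- fits$s2
  pos <- is.finite(s2) & s2 > 0
  if (is.null(prior)) prior <- fit_variance_prior(s2[pos], fits$df_residual)
  d0 <- prior$d0; s0 <- prior$s0_sq
  dg <- fits$df_residual
  s_tilde2 <- if (is.finite(d0)) (d0 * s0 + dg * s2) / (d0 + dg)
              else rep(s0, length(s2))
  df_total <- if (is.finite(d0)) d0 + dg else Inf

  features <- colnames(fits$beta) %||% paste0("f", seq_along(s2))
  if (length(test_cols) == 1L) {
    unscaled_se <- sqrt(fits$XtX_inv[test_cols, test_cols])
    coef <- fits$beta[test_cols, ]
    se <- sqrt(s2) * unscaled_se
    t_ord <- coef / se
    t_mod <- coef / (sqrt(s_tilde2) * unscaled_se)
    p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)  # df = Inf -> normal
    res <- data.frame(feature = features, coef = coef, se = se,
                      t_ordinary = t_ord, t_moderated = t_mod,
                      df_residual = dg, df_total = df_total,
                      p_raw = p_raw, stringsAsFactors = FALSE)
  } else {
    # moderated omnibus F over the group columns
    V <- fits$XtX_inv[test_cols, test_cols]
    B <- fits$beta[test_cols, , drop = FALSE]
    Vi <- solve(V)
    quad <- colSums((Vi %*% B) * B)
    q <- length(test_cols)
    F_ord <- quad / (q * s2)
    F_mod <- quad / (q * s_tilde2)
    p_raw <- stats::pf(F_mod, q, df_total, lower.tail = FALSE)
    res <- data.frame(feature = features,
                      coef = B[1, ], se = sqrt(s2 * V[1, 1]),
                      t_ordinary = sqrt(pmax(F_ord, 0)),
                      t_moderated = sqrt(pmax(F_mod, 0)),
                      df_residual = dg, df_total = df_total,
                      p_raw = p_raw, stringsAsFactors = FALSE)
  }
  # degenerate zero-variance features: perfect fits, flagged
  if (any(!pos)) {
    res$p_raw[!pos] <- ifelse(abs(res$coef[!pos]) > 0, 0, 1)
    res$zero_variance <- !pos
  }
  res$p_adj <- adjust_bh(res$p_raw)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' and stable ties.
#'
#' @param p_raw vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p_raw) {
  if (any(!is.finite(p_raw)) || any(p_raw < 0 | p_raw > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Covariate-adjusted moderated differential abundance
#'
#' Convenience wrapper: build the design for a contrast, fit per-feature
#' linear models on the (already center-scaled) feature matrix, fit the
#' moderation prior, and test.
#'
#' @param values samples x features matrix (e.g. `scaled_values` of a
#'   `normalized_table`, or scaled ratio features).
#' @param meta cohort metadata (superset of the matrix's samples).
#' @param contrast `c(groupA, groupB)` or `"three_group"`.
#' @param alpha adjusted-significance threshold.
#' @return a `diff_result` data.frame.
#' @export
diff_abundance <- function(values, meta, contrast, alpha = 0.05) {
  meta <- validate_metadata(meta)
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata is missing some samples of the feature matrix")
  X <- build_design(meta, contrast)
  Y <- values[attr(X, "samples"), , drop = FALSE]
  fits <- fit_linear_models(Y, X)
  moderated_test(fits, alpha = alpha)
}

#' Pairwise two-sample tests per feature
#'
#' Welch's two-sided t test or the Wilcoxon rank-sum test (exact for
#' combined n <= 20 without ties, tie-corrected normal approximation with
#' continuity correction otherwise) for a two-group comparison without
#' covariates.
#'
#' @param values samples x features matrix.
#' @param meta cohort metadata.
#' @param groupA,groupB group labels.
#' @param method `"student_t"` (Welch) or `"wilcoxon"`.
#' @return named vector of two-sided p-values.
#' @export
pairwise_tests <- function(values, meta, groupA, groupB,
                           method = c("student_t", "wilcoxon")) {
  method <- match.arg(method)
  meta <- validate_metadata(meta)
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  ia <- which(meta$group == groupA); ib <- which(meta$group == groupB)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least two samples")
  apply(values, 2L, function(y) {
    if (method == "student_t") {
      if (stats::sd(y[ia]) == 0 && stats::sd(y[ib]) == 0)
        return(if (mean(y[ia]) == mean(y[ib])) 1 else 0)
      stats::t.test(y[ia], y[ib], var.equal = FALSE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(y[ia], y[ib], correct = TRUE)$p.value)
    }
  })
}
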