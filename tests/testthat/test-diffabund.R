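test_that("design matrices have the documented shape and fail on rank deficiency", {
  meta <- small_cohort()
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  expect_equal(dim(X), c(20L, 4L))
  expect_setequal(colnames(X),
                  c("(Intercept)", "groupCANCER", "age_at_consent", "sexM"))
  X3 <- build_design(meta, "three_group")
  expect_equal(dim(X3), c(30L, 5L))
  expect_length(attr(X3, "test_cols"), 2L)
  # all-female cohort: sex column is constant
  allf <- generate_cohort(5L, 5L, seed = 2L)
  expect_error(build_design(allf, c("ASD_DD", "CANCER")),
               "rank deficient.*sexM")
  expect_error(build_design(meta, c("ASD_DD", "NOPE")), "contrast")
})

test_that("per-feature OLS matches the normal-equations oracle", {
  meta <- small_cohort(seed = 3L)
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  set.seed(31)
  Y <- matrix(rnorm(nrow(X) * 12), nrow(X), 12,
              dimnames = list(attr(X, "samples"), paste0("f", 1:12)))
  fits <- fit_linear_models(Y, X)
  for (j in c(1, 5, 12)) {
    expect_equal(unname(fits$beta[, j]),
                 unname(drop(oracle_ols(unclass(X)[, ], Y[, j]))),
                 tolerance = 1e-8)
  }
  expect_equal(fits$df_residual, nrow(X) - ncol(X))
  # residual variance of a perfect fit is zero
  Yp <- cbind(Y, perfect = X[, "age_at_consent"])
  fits2 <- fit_linear_models(Yp, X)
  expect_equal(unname(fits2$s2["perfect"]), 0, tolerance = 1e-20)
})

test_that("planted coefficients are recovered without bias", {
  meta <- small_cohort(seed = 4L)
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  g <- X[, "groupCANCER"]
  set.seed(42)
  Y <- sapply(1:500, function(i) 1 * g + rnorm(nrow(X), 0, 0.5))
  rownames(Y) <- attr(X, "samples")
  fits <- fit_linear_models(Y, X)
  expect_lt(abs(mean(fits$beta["groupCANCER", ]) - 1), 0.05)
})

test_that("trigamma inversion agrees with a bisection oracle", {
  for (x in c(1e-4, 0.01, 0.13, 1, 7, 1e3)) {
    expect_equal(trigamma_inverse(x), oracle_trigamma_inverse(x),
                 tolerance = 1e-8)
    expect_equal(trigamma(trigamma_inverse(x)), x, tolerance = 1e-8)
  }
})

test_that("variance prior: identical variances give infinite d0, simulation recovers (d0, s0^2)", {
  pr <- fit_variance_prior(rep(2, 50), df = 16L)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 2 * exp(-digamma(8) + log(8)), tolerance = 1e-12)
  # scaled-inverse-chi-square prior: sigma^2 = s0^2 * d0 / chisq(d0),
  # observed s^2 = sigma^2 * chisq(dg) / dg
  set.seed(7)
  d0 <- 4; s0 <- 1; dg <- 16L; m <- 5000L
  sigma2 <- s0 * d0 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, dg) / dg
  pr2 <- fit_variance_prior(s2, dg)
  expect_lt(abs(pr2$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr2$s0_sq - s0) / s0, 0.10)
})

test_that("moderation shrinks toward the prior and matches limma", {
  skip_if_not_installed("limma")
  meta <- small_cohort(seed = 6L)
  tabs <- small_tables(meta, seed = 6L, n_cell_mets = 120L)
  norm <- normalize_matrix(tabs$cells)
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  Y <- norm$log_values[attr(X, "samples"), ]
  fits <- fit_linear_models(Y, X)
  prior <- fit_variance_prior(fits$s2, fits$df_residual)
  res <- moderated_test(fits, prior)
  lf <- limma::lmFit(t(Y), unclass(X))
  eb <- limma::eBayes(lf)
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_moderated, unname(eb$t[, "groupCANCER"]),
               tolerance = 1e-8)
  expect_equal(res$p_raw, unname(eb$p.value[, "groupCANCER"]),
               tolerance = 1e-8)
  # shrinkage direction: |t_mod| <= |t_ord| iff s_g^2 < s0^2
  smaller <- fits$s2 < prior$s0_sq
  expect_true(all((abs(res$t_moderated) <= abs(res$t_ordinary) + 1e-12) == smaller))
  expect_true(all(sign(res$t_moderated) == sign(res$t_ordinary)))
})

test_that("moderated omnibus F matches limma's F test", {
  skip_if_not_installed("limma")
  meta <- small_cohort(seed = 8L)
  tabs <- small_tables(meta, seed = 8L)
  norm <- normalize_matrix(tabs$media)
  X <- build_design(meta, "three_group")
  Y <- norm$log_values[attr(X, "samples"), ]
  fits <- fit_linear_models(Y, X)
  res <- moderated_test(fits)
  eb <- limma::eBayes(limma::lmFit(t(Y), unclass(X)))
  ltop <- limma::topTable(eb, coef = attr(X, "test_cols"), number = Inf,
                          sort.by = "none")
  expect_equal(res$t_moderated^2, ltop$F, tolerance = 1e-8)
  expect_equal(res$p_raw, ltop$P.Value, tolerance = 1e-8)
})

test_that("d0 limits: zero moderation and complete pooling", {
  meta <- small_cohort(seed = 9L)
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  set.seed(90)
  Y <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(attr(X, "samples"), paste0("f", 1:30)))
  fits <- fit_linear_models(Y, X)
  # d0 -> 0: moderated equals ordinary
  r0 <- moderated_test(fits, structure(list(d0 = 1e-12, s0_sq = 1),
                                       class = "moderation_prior"))
  expect_equal(r0$t_moderated, r0$t_ordinary, tolerance = 1e-4)
  # d0 = Inf: every feature tested against the common s0^2
  rI <- moderated_test(fits, structure(list(d0 = Inf, s0_sq = 0.7),
                                       class = "moderation_prior"))
  expect_equal(rI$t_moderated * sqrt(0.7),
               unname(rI$t_ordinary * sqrt(fits$s2)), tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.4), 0.4)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^2
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(sort(adj)) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise tests: exact Wilcoxon enumeration and Welch oracle", {
  meta <- small_cohort()[c(1:3, 11:13), ]
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                 dimnames = list(meta$sample_id, "f1"))
  pw <- pairwise_tests(vals, meta, "ASD_DD", "CANCER", "wilcoxon")
  expect_equal(unname(pw), 0.1)  # 2/20 assignments as extreme
  expect_equal(unname(pw),
               oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))
  # identical samples in both groups -> p = 1
  vals2 <- matrix(rep(c(5, 6, 7), 2), 6, 1,
                  dimnames = list(meta$sample_id, "f1"))
  expect_equal(unname(pairwise_tests(vals2, meta, "ASD_DD", "CANCER",
                                     "wilcoxon")), 1)
  # Welch t against the closed form
  set.seed(5)
  meta10 <- small_cohort()
  y <- rnorm(30)
  vals3 <- matrix(y, 30, 1, dimnames = list(meta10$sample_id, "f1"))
  a <- y[meta10$group == "ASD_DD"]; b <- y[meta10$group == "CANCER"]
  se <- sqrt(var(a) / 10 + var(b) / 10)
  dfw <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  p_oracle <- 2 * pt(-abs((mean(a) - mean(b)) / se), dfw)
  expect_equal(unname(pairwise_tests(vals3, meta10, "ASD_DD", "CANCER",
                                     "student_t")), p_oracle,
               tolerance = 1e-10)
})

test_that("moderation beats the ordinary t at tiny n with dispersed variances", {
  # 3 samples/group, feature variances drawn from an inverse-chi-square
  # prior: the moderated test should recover more planted effects at
  # matched Benjamini-Hochberg FDR than the ordinary t.
  set.seed(123)
  n_rep <- 60L
  meta <- generate_cohort(3L, 2L, seed = 1L)
  meta <- meta[meta$group %in% c("ASD_DD", "CANCER"), ]
  X <- build_design(meta, c("ASD_DD", "CANCER"))
  g <- X[, "groupCANCER"]
  wins_mod <- 0L; wins_ord <- 0L
  for (r in seq_len(n_rep)) {
    m <- 150L; m_true <- 15L
    sigma2 <- 1 * 4 / rchisq(m, 4)
    beta <- c(rep(2.5, m_true), rep(0, m - m_true))
    Y <- sapply(seq_len(m), function(j)
      beta[j] * g + rnorm(6, 0, sqrt(sigma2[j])))
    rownames(Y) <- attr(X, "samples")
    fits <- fit_linear_models(Y, X)
    res <- moderated_test(fits)
    p_ord <- 2 * pt(-abs(res$t_ordinary), fits$df_residual)
    hits_mod <- sum(adjust_bh(res$p_raw)[1:m_true] < 0.05)
    hits_ord <- sum(adjust_bh(p_ord)[1:m_true] < 0.05)
    wins_mod <- wins_mod + hits_mod
    wins_ord <- wins_ord + hits_ord
  }
  expect_gt(wins_mod, wins_ord)
})
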