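test_that("linear-dependency removal drops duplicates and exact combinations", {
  set.seed(30)
  A <- rnorm(20); B <- rnorm(20)
  X <- cbind(a = A, b = B, dup = A, comb = A + B, c = rnorm(20))
  Xr <- remove_linear_correlated(X, threshold = 0.99)
  expect_equal(qr(Xr)$rank, ncol(Xr))         # full rank preserved
  expect_equal(ncol(Xr), 3L)                  # rank of X is 3
  expect_length(attr(Xr, "removed"), 2L)
  # independent Gaussian columns at n >> p survive untouched
  X2 <- matrix(rnorm(2000), 200, 10, dimnames = list(NULL, paste0("f", 1:10)))
  expect_equal(ncol(remove_linear_correlated(X2, 0.90)), 10L)
  # greedy pairwise pruning removes one of a nearly-duplicated pair
  X3 <- cbind(x = A, y = A + rnorm(20, 0, 0.01), z = rnorm(20))
  X3r <- remove_linear_correlated(X3, threshold = 0.90)
  expect_equal(ncol(X3r), 2L)
  expect_true("z" %in% colnames(X3r))
  # never increases feature count
  expect_lte(ncol(remove_linear_correlated(X3)), ncol(X3))
})

test_that("PCA reduction honors the variance threshold", {
  set.seed(31)
  # exactly collinear two-feature data: one component carries everything
  a <- rnorm(15)
  X <- cbind(a, 2 * a)
  sc <- pca_reduce(X, 0.95)
  expect_equal(attr(sc, "k"), 1L)
  # isotropic Gaussian: threshold 0.95 needs >= 4 of 5 components
  for (s in 1:5) {
    set.seed(s)
    Xi <- matrix(rnorm(500), 100, 5)
    expect_gte(attr(pca_reduce(Xi, 0.95), "k"), 4L)
  }
  # score covariance is diagonal
  Xr <- matrix(rnorm(200), 20, 10)
  sc2 <- pca_reduce(Xr, 1.0)
  cv <- cov(sc2)
  expect_equal(max(abs(cv[upper.tri(cv)])), 0, tolerance = 1e-9)
  # component count never exceeds min(n - 1, p)
  expect_lte(attr(pca_reduce(Xr, 1.0), "k"), min(19L, 10L))
  expect_error(pca_reduce(Xr, 0), "variance_threshold")
})

test_that("LogitBoost separates separable data and is antisymmetric in the labels", {
  X <- matrix(c(1:10), 10, 1)
  y <- factor(rep(c("A", "B"), each = 5))
  fit <- fit_logitboost(X, y, n_iter = 10L)
  expect_equal(as.character(predict(fit, X)), as.character(y))
  # committee score flips sign under label swap
  y2 <- factor(rep(c("B", "A"), each = 5), levels = c("A", "B"))
  fit2 <- fit_logitboost(X, y2, n_iter = 10L)
  s1 <- predict(fit, X, type = "score")
  s2 <- predict(fit2, X, type = "score")
  expect_equal(s1, -s2, tolerance = 1e-10)
  expect_error(fit_logitboost(X, rep("A", 10)), "two classes")
})

test_that("LOOCV contract: one held-out prediction per sample, order invariant", {
  set.seed(33)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  X[11:20, 1] <- X[11:20, 1] + 4
  y <- factor(rep(c("ASD_DD", "CANCER"), each = 10))
  cv <- loocv(X, y, iter_grid = c(5L, 11L))
  expect_length(cv$predictions, 20L)
  expect_equal(mean(cv$predictions == y), 1.0)  # cleanly separated
  # permuting sample order permutes predictions identically
  perm <- sample(20)
  cv_p <- loocv(X[perm, ], y[perm], iter_grid = c(5L, 11L))
  expect_equal(as.character(cv_p$predictions),
               as.character(cv$predictions)[perm])
  # three-class task runs one-vs-rest committees
  y3 <- factor(rep(c("A", "B", "C"), c(7, 7, 6)))
  X3 <- cbind(rnorm(20, rep(c(0, 4, 8), c(7, 7, 6)), 0.5), rnorm(20))
  cv3 <- loocv(X3, y3, iter_grid = 11L)
  expect_gt(mean(cv3$predictions == y3), 0.9)
})

test_that("nested and paper-mode feature extraction both run for every variant", {
  set.seed(34)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("s", 1:20), paste0("f", 1:10)))
  X[11:20, 1:3] <- X[11:20, 1:3] + 3
  y <- factor(rep(c("ASD_DD", "CANCER"), each = 10))
  for (variant in c("ALL_SIG", "REMOVE_LINEAR_CORRELATED", "PCA")) {
    cv <- loocv(X, y, variant = variant, iter_grid = 11L)
    expect_length(cv$predictions, 20L)
    cvn <- loocv(X, y, variant = variant, iter_grid = 11L, nested = TRUE)
    expect_length(cvn$predictions, 20L)
    expect_gte(mean(cv$predictions == y), 0.8)
  }
})

test_that("confusion reports reproduce the printed performance arithmetic", {
  # TP = 9, FN = 1, TN = 10, FP = 0 with positive class CANCER
  truth <- factor(c(rep("CANCER", 10), rep("ASD_DD", 10)),
                  levels = c("ASD_DD", "CANCER"))
  pred <- factor(c(rep("CANCER", 9), "ASD_DD", rep("ASD_DD", 10)),
                 levels = c("ASD_DD", "CANCER"))
  rep_ <- confusion_report(pred, truth, positive_class = "CANCER")
  expect_equal(rep_$overall_accuracy, 0.95)
  expect_equal(rep_$sensitivity, 0.90)
  expect_equal(rep_$specificity, 1.00)
  expect_true(rep_$ci95[1] <= 0.95 && 0.95 <= rep_$ci95[2])
  # all correct, n = 20: exact Clopper-Pearson lower bound
  perfect <- confusion_report(truth, truth)
  expect_equal(perfect$ci95, oracle_clopper_pearson(20, 20),
               tolerance = 1e-6)
  expect_equal(perfect$ci95[1], 0.832, tolerance = 1e-3)
  expect_equal(perfect$ci95[2], 1.0)
  # 19/20 correct vs NIR 0.5: one-sided binomial tail 21 * 0.5^20
  rep2 <- confusion_report(pred, truth)
  expect_equal(rep2$nir, 0.5)
  expect_equal(rep2$p_vs_nir, 21 * 0.5^20, tolerance = 1e-12)
  # metrics recomputable from the emitted confusion matrix alone
  cm <- rep_$confusion
  expect_equal(rep_$overall_accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(rep_$sensitivity, cm["CANCER", "CANCER"] / sum(cm["CANCER", ]))
  expect_equal(rep_$specificity, cm["ASD_DD", "ASD_DD"] / sum(cm["ASD_DD", ]))
  # three-class reports carry per-class one-vs-rest metrics
  t3 <- factor(rep(c("A", "B", "C"), each = 4))
  r3 <- confusion_report(t3, t3, positive_class = "A")
  expect_length(r3$sensitivity, 3L)
  expect_equal(unname(r3$sensitivity), rep(1, 3))
  expect_error(confusion_report(pred[1:5], truth), "same length")
})

test_that("label-permuted LOOCV accuracy stays near the no-information rate", {
  set.seed(35)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(paste0("s", 1:20), NULL))
  y <- factor(rep(c("ASD_DD", "CANCER"), each = 10))
  accs <- replicate(30, {
    yp <- sample(y)
    mean(loocv(X, yp, iter_grid = 11L)$predictions == yp)
  })
  nir <- 0.5
  band <- 2 * sqrt(nir * (1 - nir) / 20) / sqrt(30)
  expect_lt(abs(mean(accs) - nir), 3 * band + 0.05)
})

test_that("the performance grid emits one row per source x grouping x variant", {
  meta <- small_cohort(seed = 36L)
  set.seed(36)
  vals <- matrix(rnorm(30 * 8), 30, 8,
                 dimnames = list(meta$sample_id, paste0("f", 1:8)))
  vals[meta$group == "CANCER", 1:4] <- vals[meta$group == "CANCER", 1:4] + 3
  fsets <- list(
    cells = list(values = vals,
                 significant = list(two_group = paste0("f", 1:4),
                                    three_group = paste0("f", 1:4))),
    media = list(values = vals,
                 significant = list(two_group = character(),
                                    three_group = character())))
  out <- performance_grid(fsets, meta, load_config())
  expect_equal(nrow(out$grid), 12L)
  expect_true(all(is.na(out$grid$accuracy[out$grid$source == "media"])))
  cells2 <- out$grid[out$grid$source == "cells" &
                     out$grid$grouping == "two_group", ]
  expect_true(all(cells2$accuracy > 0.8))
  expect_true(all(out$grid$n_features[out$grid$source == "media"] == 0L))
})
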