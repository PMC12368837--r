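test_that("PCA recovers rank-1 structure and stays orthonormal", {
  set.seed(1)
  u <- rnorm(15); v <- rnorm(40)
  X <- outer(u, v)
  f <- fit_pca(X, 3)
  expect_equal(f$explained[1], 1, tolerance = 1e-10)
  expect_equal(colMeans(f$scores), rep(0, 3), tolerance = 1e-12)
  expect_equal(crossprod(f$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("full-rank PCA reconstructs the data", {
  set.seed(2)
  X <- matrix(rnorm(20 * 8), 20, 8)
  f <- fit_pca(X, 8)
  rec <- f$scores %*% t(f$loadings) + rep(1, 20) %o% f$center
  expect_lt(max(abs(rec - X)), 1e-10)
  expect_error(fit_pca(X, 20), "exceeds")
})

test_that("wide-matrix Gram path agrees with the reference SVD", {
  set.seed(3)
  X <- matrix(rnorm(12 * 200), 12, 200)  # bins >> samples
  f <- fit_pca(X, 5)
  pr <- prcomp(X)
  for (j in 1:5) {
    agree <- max(abs(f$loadings[, j] - pr$rotation[, j]))
    flip <- max(abs(f$loadings[, j] + pr$rotation[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  expect_equal(f$explained,
               (pr$sdev^2 / sum(pr$sdev^2))[1:5], tolerance = 1e-8)
})

test_that("PCA-LDA separates well-separated Gaussians perfectly", {
  d <- gaussian_classes(n_per_class = 20, sep = 10, seed = 3)
  fit <- fit_pca_lda(d$X, d$labels, k = 5)
  expect_equal(ncol(fit$discriminants), 1)  # classes - 1
  pred <- predict(fit, d$X)
  expect_equal(mean(pred == d$labels), 1)
})

test_that("PCA-LDA fitting is deterministic", {
  d <- gaussian_classes(seed = 9)
  f1 <- fit_pca_lda(d$X, d$labels, k = 6)
  f2 <- fit_pca_lda(d$X, d$labels, k = 6)
  expect_identical(f1$discriminants, f2$discriminants)
  expect_identical(f1$centroids, f2$centroids)
  expect_error(fit_pca_lda(d$X, rep("a", nrow(d$X))), "two classes")
})

test_that("permuted labels give chance-level cross-validation", {
  d <- gaussian_classes(n_per_class = 20, sep = 10, seed = 5)
  set.seed(13)
  perm <- sample(d$labels)
  fm <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)), perm)
  cv <- cross_validate(fm, n_repeats = 25, seed = 13, k = 5)
  acc <- 100 * sum(diag(cv$confusion)) / sum(cv$confusion)
  expect_gt(acc, 30)
  expect_lt(acc, 70)
})

test_that("cross-validation holds out a stratified fifth and is seeded", {
  d <- gaussian_classes(n_per_class = 25, sep = 8, seed = 6)
  fm <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)), d$labels)
  lab <- factor(d$labels)
  set.seed(99)
  idx <- lareims:::split_test_idx(lab, NULL)
  expect_equal(sum(lab[idx] == "a"), 5)  # 20% of 25 per class
  expect_equal(sum(lab[idx] == "b"), 5)

  cv1 <- cross_validate(fm, n_repeats = 5, seed = 3, k = 5)
  cv2 <- cross_validate(fm, n_repeats = 5, seed = 3, k = 5)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_equal(cv1$sensitivity, 100)
  expect_equal(cv1$specificity, 100)
})

test_that("group-aware splits hold out whole specimens", {
  d <- gaussian_classes(n_per_class = 20, sep = 8, seed = 12)
  groups <- rep(paste0("g", 1:8), each = 5)
  fm <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)), d$labels,
                       groups = groups)
  set.seed(4)
  idx <- lareims:::split_test_idx(factor(d$labels), groups)
  held <- unique(groups[idx])
  expect_true(all(table(groups[idx])[held] == 5))  # whole groups only
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  for (s in 1:5) {
    set.seed(s)
    nc <- sample(2:3, 1)
    n <- 20 * nc; p <- 10
    mu <- matrix(rnorm(nc * p, sd = 3), nc, p)
    X <- do.call(rbind, lapply(1:nc, function(i)
      matrix(rnorm(20 * p), 20, p) + rep(1, 20) %o% mu[i, ]))
    lab <- rep(letters[1:nc], each = 20)
    mine <- predict(fit_pca_lda(X, lab, k = p), X)
    ref <- predict(MASS::lda(X, grouping = lab), X)$class
    expect_equal(as.character(mine), as.character(ref))
  }
})

test_that("cross-modality transfer reproduces training performance on A = B", {
  d <- gaussian_classes(n_per_class = 20, sep = 10, seed = 7)
  fm <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)), d$labels, "laser")
  res <- cross_modality_eval(fm, fm, k = 5)
  expect_equal(res$correct_pct, c(100, 100))

  other <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)) + 0.5,
                          d$labels, "diathermy")
  expect_error(cross_modality_eval(fm, other), "bin axes")
})

test_that("confusion metrics follow the TP/FN/TN/FP arithmetic", {
  truth <- c(rep("pos", 10), rep("neg", 20))
  pred <- c(rep("pos", 9), "neg", "pos", rep("neg", 19))
  m <- confusion_metrics(truth, pred, positive = "pos")
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 95)

  all_right <- confusion_metrics(truth, truth, positive = "pos")
  expect_equal(c(all_right$sensitivity, all_right$specificity), c(100, 100))

  none <- confusion_metrics(rep("neg", 5), rep("neg", 5), positive = "pos")
  expect_true(is.na(none$sensitivity))
  expect_match(none$undefined, "sensitivity")
})

test_that("volcano flags nothing for identical groups", {
  set.seed(10)
  half <- matrix(rlnorm(20 * 50), 20, 50)
  X <- rbind(half, half)
  lab <- rep(c("a", "b"), each = 20)
  v <- volcano(X, lab)
  expect_equal(v$log2_fc, rep(0, 50))
  expect_true(all(v$q > 0.9))
  expect_equal(sum(v$significant), 0)
  expect_true(all(v$q >= v$p))
})

test_that("volcano recovers a strongly planted bin", {
  set.seed(5)
  X <- matrix(rlnorm(40 * 100, sdlog = 0.4), 40, 100)
  X[1:20, 37] <- X[1:20, 37] * 10
  v <- volcano(X, factor(rep(c("up", "ref"), each = 20),
                         levels = c("up", "ref")))
  expect_true(v$significant[37])
  expect_gt(v$log2_fc[37], 1)
  expect_error(volcano(X[c(1:2, 21:40), ], rep(c("up", "ref"), c(2, 20))),
               "three samples")
})

test_that("tidiers return tibbles with the expected shape", {
  d <- gaussian_classes(seed = 15)
  fit <- fit_pca_lda(d$X, d$labels, k = 4)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_lte(glance(fit)$explained_total, 1 + 1e-12)

  fm <- feature_matrix(d$X - min(d$X), seq_len(ncol(d$X)), d$labels)
  cv <- cross_validate(fm, n_repeats = 3, seed = 1, k = 4)
  expect_equal(nrow(tidy(cv)), 2)
  expect_true(all(c("sensitivity", "specificity") %in% names(glance(cv))))

  set.seed(30)
  X <- matrix(rlnorm(30 * 20), 30, 20)
  v <- volcano(X, rep(c("a", "b"), each = 15))
  expect_equal(glance(v)$n_bins, 20)
  expect_s3_class(autoplot(v), "ggplot")
})
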