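#' Feature matrix of binned spectra
#'
#' Samples-by-bins container for supervised analysis: a non-negative
#' intensity matrix, the shared bin axis, a class label per sample and an
#' optional modality tag.
#'
#' @param values Numeric matrix, samples x bins, non-negative.
#' @param bin_lo Bin lower edges (length `ncol(values)`).
#' @param labels Class labels, length `nrow(values)`.
#' @param modality Modality tag(s), recycled to the number of samples.
#' @param groups Optional grouping unit (e.g. specimen) per sample, used by
#'   [cross_validate()] to split by group instead of by sample.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, bin_lo, labels, modality = "laser",
                           groups = NULL) {
  values <- as.matrix(values)
  abort_if(any(values < 0), "feature matrix entries must be non-negative")
  abort_if(length(bin_lo) != ncol(values),
           "bin axis length must match the number of columns")
  abort_if(length(labels) != nrow(values),
           "one label per sample is required")
  structure(list(values = values, bin_lo = bin_lo,
                 labels = factor(labels),
                 modality = rep_len(modality, nrow(values)),
                 groups = groups),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d bins; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (%d)", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Convert an image grid plus label image to a feature matrix
#'
#' @param grid An [reconstruct_image()] grid.
#' @param labels A `rows x cols` label matrix (e.g. from [gen_phantom()]),
#'   or a vector in row-major pixel order.
#' @param drop Classes to drop (e.g. `"background"`).
#' @inheritParams feature_matrix
#' @return A [feature_matrix()].
#' @export
as_feature_matrix <- function(grid, labels, modality = grid$modality,
                              drop = "background", groups = NULL) {
  lab <- if (is.matrix(labels)) as.vector(t(labels)) else labels
  abort_if(length(lab) != nrow(grid$values),
           "label image does not match the grid")
  keep <- !(lab %in% drop)
  feature_matrix(grid$values[keep, , drop = FALSE], grid$bin_lo, lab[keep],
                 modality = modality,
                 groups = if (!is.null(groups)) groups[keep])
}

fm_values <- function(X) if (inherits(X, "feature_matrix")) X$values else as.matrix(X)

fm_field <- function(X, name) {
  if (inherits(X, "feature_matrix")) X[[name]] else NULL
}

#' Principal component analysis of spectra
#'
#' Mean-centering followed by singular value decomposition. When there are
#' more bins than samples the decomposition is computed from the sample Gram
#' matrix, which is exact and much faster for wide spectra. Component signs
#' are fixed so each component's largest-magnitude loading is positive.
#'
#' @param X A [feature_matrix()] or numeric matrix (samples x bins).
#' @param k Number of components to keep.
#' @return An object of class `pca_fit`: `center`, `loadings` (bins x k,
#'   orthonormal), `scores` (samples x k), `sdev`, `explained` (variance
#'   shares of the kept components).
#' @export
fit_pca <- function(X, k) {
  V <- fm_values(X)
  n <- nrow(V); p <- ncol(V)
  abort_if(k > min(n - 1, p),
           sprintf("k = %d exceeds min(samples - 1, bins) = %d",
                   k, min(n - 1, p)))
  ctr <- colMeans(V)
  Xc <- sweep(V, 2, ctr)
  if (p > n) {
    G <- tcrossprod(Xc)          # n x n
    eg <- eigen(G, symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    U <- eg$vectors
    loadings <- crossprod(Xc, U[, seq_len(k), drop = FALSE]) %*%
      diag(1 / pmax(d[seq_len(k)], max(d) * 1e-12), k)
    # null components (zero singular value) get arbitrary directions from
    # the division above; re-orthonormalize while preserving the leading
    # columns' directions
    qq <- qr(loadings)
    Q <- qr.Q(qq)
    sgn <- sign(diag(qr.R(qq)))
    sgn[sgn == 0] <- 1
    loadings <- Q %*% diag(sgn, k)
    sdev_all <- d / sqrt(max(n - 1, 1))
  } else {
    sv <- svd(Xc, nu = k, nv = k)
    loadings <- sv$v
    sdev_all <- sv$d / sqrt(max(n - 1, 1))
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- Xc %*% loadings
  tot_var <- sum(sdev_all^2)
  structure(list(center = ctr, loadings = loadings, scores = scores,
                 sdev = sdev_all[seq_len(k)],
                 explained = if (tot_var > 0) sdev_all[seq_len(k)]^2 / tot_var
                             else rep(0, k),
                 k = k),
            class = "pca_fit")
}

#' Fit a PCA-LDA classifier
#'
#' Linear discriminant analysis on the first `k` principal-component scores:
#' within-class scatter (ridge-regularized by `1e-6` times its trace) and
#' between-class scatter define up to `classes - 1` discriminant directions;
#' classification is by the nearest class centroid in discriminant space
#' (Euclidean).
#'
#' @param X A [feature_matrix()] or numeric matrix.
#' @param labels Class labels (ignored when `X` is a feature matrix).
#' @param k Number of principal components (default 10, capped at
#'   `samples - classes`).
#' @return An object of class `pca_lda`: the PCA fit, discriminant
#'   directions, class centroids and levels.
#' @export
fit_pca_lda <- function(X, labels = NULL, k = 10) {
  V <- fm_values(X)
  lab <- factor(labels %||% fm_field(X, "labels"))
  abort_if(nlevels(lab) < 2, "PCA-LDA requires at least two classes")
  abort_if(any(tabulate(lab) < 2), "every class needs at least two samples")
  k <- min(k, nrow(V) - nlevels(lab), ncol(V))
  pca <- fit_pca(V, k)
  S <- pca$scores
  cl <- levels(lab)
  grand <- colMeans(S)
  Sw <- matrix(0, k, k); Sb <- matrix(0, k, k)
  means <- matrix(0, length(cl), k, dimnames = list(cl, NULL))
  for (g in cl) {
    Sg <- S[lab == g, , drop = FALSE]
    mg <- colMeans(Sg)
    means[g, ] <- mg
    Cg <- sweep(Sg, 2, mg)
    Sw <- Sw + crossprod(Cg)
    Sb <- Sb + nrow(Sg) * tcrossprod(mg - grand)
  }
  Sw <- Sw + 1e-6 * sum(diag(Sw)) * diag(k)
  ev <- eigen(solve(Sw, Sb))
  n_disc <- min(length(cl) - 1, k)
  W <- Re(ev$vectors[, seq_len(n_disc), drop = FALSE])
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  centroids <- means %*% W
  structure(list(pca = pca, discriminants = W, centroids = centroids,
                 levels = cl, k = k),
            class = "pca_lda")
}

#' @export
predict.pca_lda <- function(object, newdata, ...) {
  V <- fm_values(newdata)
  S <- sweep(V, 2, object$pca$center) %*% object$pca$loadings
  D <- S %*% object$discriminants
  d2 <- outer(rowSums(D^2), rowSums(object$centroids^2), "+") -
    2 * D %*% t(object$centroids)
  factor(object$levels[max.col(-d2, ties.method = "first")],
         levels = object$levels)
}

#' Sensitivity and specificity of a prediction
#'
#' `sensitivity = 100 TP / (TP + FN)`, `specificity = 100 TN / (TN + FP)`
#' for the designated positive class. A zero denominator yields `NA` and
#' the metric is listed in the `undefined` column.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param positive The positive class.
#' @return A one-row tibble: `sensitivity`, `specificity` (percent),
#'   `undefined` (comma-separated names of undefined metrics, or `""`).
#' @export
confusion_metrics <- function(truth, predicted, positive) {
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos); fp <- sum(!truth_pos & pred_pos)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  undef <- c(if (tp + fn == 0) "sensitivity", if (tn + fp == 0) "specificity")
  tibble::tibble(sensitivity = sens, specificity = spec,
                 undefined = paste(undef, collapse = ","))
}

# stratified indices of one repeated 80/20 split; by group when available
split_test_idx <- function(lab, groups = NULL, frac = 0.2) {
  if (is.null(groups)) {
    unlist(lapply(levels(lab), function(g) {
      idx <- which(lab == g)
      sample(idx, max(1, round(frac * length(idx))))
    }), use.names = FALSE)
  } else {
    gl <- tapply(as.character(lab), groups, function(x)
      names(sort(table(x), decreasing = TRUE))[1])
    test_groups <- unlist(lapply(unique(gl), function(g) {
      gs <- names(gl)[gl == g]
      sample(gs, max(1, round(frac * length(gs))))
    }), use.names = FALSE)
    which(groups %in% test_groups)
  }
}

#' Leave-20%-out cross-validation of the PCA-LDA classifier
#'
#' Repeated stratified random 80/20 splits: in each repeat the model is
#' refitted on the 80% and evaluated on the held-out 20%, and the confusion
#' matrix is pooled over repeats. When the feature matrix carries groups
#' (e.g. specimens), whole groups are held out to avoid leakage.
#'
#' @param X A [feature_matrix()].
#' @param labels Optional label override.
#' @param n_repeats Number of random splits (default 25).
#' @param seed Integer seed.
#' @param k Number of principal components.
#' @param positive Positive class for pooled sensitivity/specificity
#'   (default: first level).
#' @return An object of class `cv_report`: pooled `confusion` table,
#'   `per_class` tibble (percent correct and one-vs-rest metrics),
#'   `sensitivity`/`specificity` (percent, for the positive class),
#'   `per_repeat` accuracies, and the scheme description.
#' @export
cross_validate <- function(X, labels = NULL, n_repeats = 25, seed = 1,
                           k = 10, positive = NULL) {
  lab <- factor(labels %||% fm_field(X, "labels"))
  abort_if(any(tabulate(lab) < 2), "every class needs at least two samples")
  positive <- positive %||% levels(lab)[1]
  V <- fm_values(X)
  set.seed(as.integer(seed))
  truth_all <- pred_all <- factor(character(0), levels = levels(lab))
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    test <- split_test_idx(lab, fm_field(X, "groups"))
    fit <- fit_pca_lda(V[-test, , drop = FALSE], lab[-test], k = k)
    pred <- predict(fit, V[test, , drop = FALSE])
    truth_all <- c(truth_all, lab[test])
    pred_all <- c(pred_all, factor(pred, levels = levels(lab)))
    per_repeat[r] <- mean(pred == lab[test])
  }
  conf <- table(truth = truth_all, predicted = pred_all)
  per_class <- purrr::map_dfr(levels(lab), function(g) {
    cm <- confusion_metrics(truth_all, pred_all, g)
    tibble::tibble(class = g,
                   n = sum(truth_all == g),
                   correct_pct = 100 * conf[g, g] / sum(conf[g, ]),
                   sensitivity = cm$sensitivity,
                   specificity = cm$specificity)
  })
  pooled <- confusion_metrics(truth_all, pred_all, positive)
  structure(list(scheme = "repeated stratified 80/20",
                 n_repeats = n_repeats, seed = seed, positive = positive,
                 confusion = conf, per_class = per_class,
                 sensitivity = pooled$sensitivity,
                 specificity = pooled$specificity,
                 per_repeat = tibble::tibble(repeat_index = seq_len(n_repeats),
                                             accuracy = per_repeat)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d repeats\n", x$scheme, x$n_repeats))
  cat(sprintf("  pooled sensitivity %.2f%%, specificity %.2f%% (positive: %s)\n",
              x$sensitivity, x$specificity, x$positive))
  print(x$confusion)
  invisible(x)
}

#' Cross-modality transfer evaluation
#'
#' Fits a PCA-LDA model on all samples of one modality and applies it,
#' unchanged, to all samples of another. Requires an identical bin axis
#' and shared label vocabulary.
#'
#' @param train,test [feature_matrix()] objects of the two modalities.
#' @param k Number of principal components.
#' @return A tibble with per-class percent correct on the test modality.
#' @export
cross_modality_eval <- function(train, test, k = 10) {
  abort_if(length(train$bin_lo) != length(test$bin_lo) ||
             any(train$bin_lo != test$bin_lo),
           "bin axes of the two modalities differ")
  abort_if(!all(levels(test$labels) %in% levels(train$labels)),
           "test labels outside the training vocabulary")
  fit <- fit_pca_lda(train, k = k)
  pred <- predict(fit, test)
  purrr::map_dfr(levels(test$labels), function(g) {
    sel <- test$labels == g
    tibble::tibble(class = g, n = sum(sel),
                   correct_pct = 100 * mean(pred[sel] == g))
  })
}

#' Univariate volcano analysis
#'
#' Per-bin log2 fold change of group means (zero-protected by a small
#' epsilon) with a two-sided Mann-Whitney U test and Benjamini-Hochberg
#' correction. A bin is significant when `q < q_threshold` and
#' `|log2FC| > fc_threshold`.
#'
#' @param X A [feature_matrix()] with exactly two classes (or a matrix
#'   plus `labels`).
#' @param labels Optional label override; must have two levels.
#' @param q_threshold FDR threshold (default 0.05).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1).
#' @param eps Zero-protection constant for the means ratio.
#' @return A tibble of class `volcano_result`: `bin_lo`, `log2_fc`, `p`,
#'   `q`, `significant`.
#' @export
volcano <- function(X, labels = NULL, q_threshold = 0.05, fc_threshold = 1,
                    eps = 1e-12) {
  V <- fm_values(X)
  lab <- factor(labels %||% fm_field(X, "labels"))
  abort_if(nlevels(lab) != 2, "volcano analysis requires exactly two groups")
  abort_if(any(tabulate(lab) < 3), "each group needs at least three samples")
  g1 <- lab == levels(lab)[1]
  m1 <- colMeans(V[g1, , drop = FALSE])
  m2 <- colMeans(V[!g1, , drop = FALSE])
  lfc <- log2((m1 + eps) / (m2 + eps))
  p <- apply(V, 2, function(col) {
    if (all(col[g1] == col[g1][1]) && all(col[!g1] == col[!g1][1]) &&
        col[g1][1] == col[!g1][1]) return(1)
    suppressWarnings(stats::wilcox.test(col[g1], col[!g1],
                                        exact = FALSE)$p.value)
  })
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    bin_lo = if (inherits(X, "feature_matrix")) X$bin_lo else seq_len(ncol(V)),
    log2_fc = lfc, p = p, q = q,
    significant = q < q_threshold & abs(lfc) > fc_threshold
  )
  attr(out, "groups") <- levels(lab)
  attr(out, "q_threshold") <- q_threshold
  attr(out, "fc_threshold") <- fc_threshold
  class(out) <- c("volcano_result", class(out))
  out
}

#' Volcano plot
#'
#' @param object A [volcano()] result.
#' @param ... Unused.
#' @return A ggplot of `-log10(q)` against log2 fold change.
#' @export
autoplot.volcano_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2_fc,
                                       y = -log10(pmax(.data$q, 1e-300)),
                                       colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(object, "fc_threshold"),
                        linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q")
}
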