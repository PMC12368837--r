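#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PCA-LDA model
#'
#' @param x A [fit_pca_lda()] object.
#' @param ... Unused.
#' @return A tibble with one row per principal component: standard
#'   deviation and explained variance share.
#' @export
tidy.pca_lda <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 sdev = x$pca$sdev,
                 explained = x$pca$explained)
}

#' @rdname tidy.pca_lda
#' @export
glance.pca_lda <- function(x, ...) {
  tibble::tibble(k = x$k,
                 n_classes = length(x$levels),
                 n_discriminants = ncol(x$discriminants),
                 explained_total = sum(x$pca$explained))
}

#' Tidy a cross-validation report
#'
#' @param x A [cross_validate()] report.
#' @param ... Unused.
#' @return Per-class percent correct and one-vs-rest metrics.
#' @export
tidy.cv_report <- function(x, ...) x$per_class

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_repeats = x$n_repeats,
                 positive = x$positive,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = 100 * sum(diag(x$confusion)) / sum(x$confusion))
}

#' Tidy a volcano result
#'
#' @param x A [volcano()] result.
#' @param ... Unused.
#' @return The per-bin tibble (already tidy).
#' @export
tidy.volcano_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.volcano_result
#' @export
glance.volcano_result <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x), n_significant = sum(x$significant),
                 q_threshold = attr(x, "q_threshold"),
                 fc_threshold = attr(x, "fc_threshold"))
}
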