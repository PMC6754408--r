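# broom-style accessors for the package's fitted objects.

#' @rdname sexdimorph-tidiers
#' @param x A fitted object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) x$table

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  tibble(method = x$method, n_genes = nrow(x$table),
         n = paste(x$n, collapse = "/"),
         n_degenerate = sum(x$table$degenerate),
         min_p_fdr = min(x$table$p_fdr))
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::tidy
tidy.anova_result <- function(x, ...) x$table

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.anova_result <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_tissues = length(x$tissues),
         ss_type = x$type)
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::tidy
tidy.do_result <- function(x, ...) x$table

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.do_result <- function(x, ...) {
  tibble(n_ocrs = nrow(x$table), window_width = x$window_width,
         min_window = x$min_window,
         n_window_expanded = sum(x$table$window_expanded),
         n_mad_fallback = sum(x$table$mad_fallback))
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::tidy
tidy.gsea_result <- function(x, ...) select(x$table, -dplyr::any_of("leading_edge"))

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.gsea_result <- function(x, ...) {
  tibble(n_sets = nrow(x$table), n_excluded = nrow(x$excluded),
         n_significant = sum(x$table$significant),
         B = x$params$B, weight = x$params$p)
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::tidy
tidy.perm_test <- function(x, ...) tibble(null_statistic = x$null)

#' Tidiers for sexdimorph result objects
#'
#' `tidy()` returns the per-unit (gene, OCR, set, permutation) table of a
#' result; `glance()` returns a one-row summary.
#'
#' @name sexdimorph-tidiers
#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.perm_test <- function(x, ...) {
  tibble(design = x$design, observed = x$observed, p = x$p,
         exceedances = x$exceedances, B = x$B, tail = x$tail,
         exhaustive = x$exhaustive)
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$variance_explained),
         variance_explained = x$variance_explained)
}

#' @rdname sexdimorph-tidiers
#' @exportS3Method generics::glance
glance.pca_result <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         total_variance_explained = sum(x$variance_explained))
}
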