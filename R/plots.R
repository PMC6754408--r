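# ggplot2 views of the result objects.

#' @rdname sexdimorph-plots
#' @param object A result object.
#' @param alpha,fc_fold Calling criteria drawn as guides on volcano-style
#'   plots.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, alpha = 0.2, fc_fold = 1.5, ...) {
  tbl <- object$table
  tbl$called <- tbl$p_fdr < alpha & abs(tbl$log2fc) > log2(fc_fold)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                    colour = .data$called)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_fold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (female - male)", y = "-log10 p",
                  colour = sprintf("pFDR < %.2g & FC > %.2g", alpha, fc_fold)) +
    ggplot2::theme_minimal()
}

#' @rdname sexdimorph-plots
#' @exportS3Method ggplot2::autoplot
autoplot.do_result <- function(object, alpha = 0.05, fc_fold = 2, ...) {
  tbl <- object$table
  tbl$called <- tbl$p_fdr < alpha & abs(tbl$log2fc) > log2(fc_fold)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mean_intensity, y = .data$log2fc,
                                    colour = .data$called)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "royalblue")) +
    ggplot2::labs(x = "mean log2 accessibility", y = "log2 fold change (F - M)",
                  colour = "differential OCR") +
    ggplot2::theme_minimal()
}

#' @rdname sexdimorph-plots
#' @exportS3Method ggplot2::autoplot
autoplot.gsea_result <- function(object, ...) {
  tbl <- object$table |> arrange(.data$nes)
  tbl$set <- factor(tbl$set, levels = tbl$set)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$nes, y = .data$set,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "seagreen")) +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  fill = sprintf("q < %.2g", object$params$q_cut)) +
    ggplot2::theme_minimal()
}

#' @rdname sexdimorph-plots
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = sprintf("permutation p = %.4g (%s)", object$p,
                                  object$design)) +
    ggplot2::theme_minimal()
}

#' Plots for sexdimorph result objects
#'
#' `autoplot()` methods: volcano plot for differential-expression results, an
#' MA-style intensity/fold-change plot for accessibility results, an NES bar
#' chart for enrichment results, a null-distribution histogram for permutation
#' tests, and score plots for PCA results.
#'
#' @name sexdimorph-plots
#' @param colour_by Optional factor (aligned to samples) colouring PCA scores.
#' @param components Two component indices to draw.
#' @rdname sexdimorph-plots
#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, colour_by = NULL,
                                components = c(1, 2), ...) {
  df <- tibble(s1 = object$scores[, components[1]],
               s2 = object$scores[, components[2]])
  if (!is.null(colour_by)) df$group <- colour_by
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  100 * object$variance_explained[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  100 * object$variance_explained[components[2]])) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) pl + ggplot2::geom_point()
  else pl + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Fold-change distribution plot for signature shift analyses
#'
#' Density plot of a fold-change vector split into signature and background
#' genes, the visual companion of [shift_test_two_sample()].
#'
#' @param fc A [fold_change_vector()] tibble.
#' @param signature Signature gene ids.
#' @return A ggplot.
#' @export
plot_signature_shift <- function(fc, signature) {
  fc$group <- ifelse(fc$gene_id %in% signature, "signature", "background")
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$log2fc, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 fold change (female - male)", y = "density") +
    ggplot2::theme_minimal()
}
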