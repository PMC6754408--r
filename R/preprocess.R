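# Normalization, filtering and PCA exploration rules applied before any
# differential testing. All scale estimates use the sample SD (n - 1)
# convention.

#' Floor at 1 and log2-transform
#'
#' Values below one are replaced by one, then everything is log2-transformed,
#' so the output is non-negative and a silent/absent gene maps to 0.
#'
#' @param x An [expr_matrix()] on the linear scale.
#' @return An [expr_matrix()] on the log2 scale.
#' @export
floor_log_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "linear") stop("floor_log_transform expects linear-scale values")
  if (any(x$values < 0)) stop("negative expression values are not allowed")
  out <- x
  out$values <- log2(pmax(x$values, 1))
  out$scale <- "log2"
  out
}

#' Noise filter
#'
#' A gene is kept iff its log2 expression is strictly above `threshold` in at
#' least `min_samples` samples (the size of the smallest comparison group).
#' Equality with the threshold does not count.
#'
#' @param x An [expr_matrix()], log2 scale.
#' @param threshold Noise threshold in log2 units (e.g. 5 or 6).
#' @param min_samples Minimum number of samples above threshold.
#' @return A list with `expr` (filtered [expr_matrix()], original gene order
#'   preserved) and `dropped` (character vector of removed gene ids).
#' @export
noise_filter <- function(x, threshold, min_samples) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "log2") stop("noise_filter expects log2-scale values")
  if (threshold < 0 || min_samples < 1) stop("invalid noise-filter spec")
  keep <- rowSums(x$values > threshold) >= min_samples
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$genes <- x$genes[keep, ]
  list(expr = out, dropped = x$genes$gene_id[!keep])
}

#' Per-gene z-score normalization
#'
#' Subtracts each gene's mean and divides by its sample SD.
#'
#' @param x An [expr_matrix()].
#' @return An [expr_matrix()] whose rows have mean 0 and SD 1.
#' @export
zscore_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  mu <- rowMeans(x$values)
  s <- apply(x$values, 1, sample_sd)
  if (any(s == 0)) {
    stop("zero-SD gene(s): ",
         paste(head(x$genes$gene_id[s == 0], 5), collapse = ", "),
         " -- drop or jitter before normalizing")
  }
  out <- x
  out$values <- (x$values - mu) / s
  out
}

#' Median-of-ratios size-factor normalization
#'
#' For each sample j, the size factor is the median over reference genes
#' (genes with nonzero counts in all samples) of `count[g, j] / geomean(g)`,
#' and normalized values are counts divided by the size factor.
#'
#' @param x An [expr_matrix()] of raw counts.
#' @return A list with `expr` (normalized, linear scale) and `size_factors`
#'   (named numeric).
#' @export
median_of_ratios_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "counts") stop("median_of_ratios_normalize expects raw counts")
  counts <- x$values
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no gene with nonzero counts in all samples")
  log_geomean <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geomean))
  })
  out <- x
  out$values <- sweep(counts, 2, sf, "/")
  out$scale <- "linear"
  list(expr = out, size_factors = sf)
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same value distribution: each
#' value is replaced by the mean across columns of the values at the same
#' rank; ties receive the mean of the implicated reference values.
#'
#' @param x An [expr_matrix()] or plain matrix.
#' @return Same type as the input, quantile-normalized.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expr_matrix")) {
    out <- x
    out$values <- limma::normalizeQuantiles(x$values, ties = TRUE)
    dimnames(out$values) <- dimnames(x$values)
    return(out)
  }
  out <- limma::normalizeQuantiles(as.matrix(x), ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Tukey median polish
#'
#' Decomposes a matrix into overall + row + column effects + residuals by
#' alternately sweeping medians out of rows then columns.
#'
#' @param x Numeric matrix, at least 2 x 2.
#' @param max_iter Maximum sweep iterations.
#' @param tol Convergence tolerance on the residual change.
#' @return A list with `overall`, `row_effects`, `col_effects`, `residuals`;
#'   the decomposition identity `x == overall + row + col + residuals` holds
#'   exactly.
#' @export
median_polish <- function(x, max_iter = 10, tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("median_polish needs at least a 2 x 2 matrix")
  fit <- stats::medpolish(x, eps = tol, maxiter = max_iter, trace.iter = FALSE)
  list(overall = fit$overall, row_effects = fit$row, col_effects = fit$col,
       residuals = fit$residuals)
}

#' Sample-wise PCA of a gene-standardized matrix
#'
#' Rows are genes (variables), columns are samples (observations). Components
#' are sign-fixed so that each component's largest-magnitude gene coefficient
#' is positive.
#'
#' @param x An [expr_matrix()] (typically z-normalized) or matrix.
#' @param n_components Number of components to retain.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `coefficients` (genes x components, unit column norm) and
#'   `variance_explained` (fractions).
#' @export
pca_decompose <- function(x, n_components = NULL) {
  vals <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  n_max <- min(dim(vals))
  n_components <- n_components %||% n_max
  if (n_components > n_max) stop("n_components exceeds min(genes, samples)")
  p <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  coefs <- p$rotation[, k, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  # sign convention: largest |coefficient| positive in every component
  for (j in seq_len(ncol(coefs))) {
    i_max <- which.max(abs(coefs[, j]))
    if (coefs[i_max, j] < 0) {
      coefs[, j] <- -coefs[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, coefficients = coefs,
                 variance_explained = ve[k]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; variance explained: %s ...\n",
              ncol(x$scores),
              paste(signif(head(x$variance_explained, 4), 3), collapse = ", ")))
  invisible(x)
}

#' Genes contributing to a principal component
#'
#' @param pca A [pca_decompose()] result.
#' @param component Component index (1-based).
#' @param threshold Absolute-coefficient cutoff (strict `>`).
#' @return Tibble of contributing genes sorted by `abs(coefficient)`
#'   descending.
#' @export
contributing_genes <- function(pca, component, threshold = 0.05) {
  stopifnot(inherits(pca, "pca_result"))
  if (component > ncol(pca$coefficients)) stop("component out of range")
  co <- pca$coefficients[, component]
  hits <- which(abs(co) > threshold)
  tibble(gene_id = rownames(pca$coefficients)[hits] %||% as.character(hits),
         coefficient = co[hits]) |>
    arrange(desc(abs(coefficient)))
}

#' First principal component separating the sexes
#'
#' Applies a paired two-sided t-test of female vs male scores on every
#' component (pairs built from `pairing_keys`), adjusts across components by
#' Benjamini-Hochberg, and returns the smallest component index with
#' pFDR < `alpha`.
#'
#' @param pca A [pca_decompose()] result whose score rows are samples.
#' @param metadata Sample metadata containing `sample_id`, `sex` and the
#'   pairing keys.
#' @param pairing_keys Metadata columns used to match female/male samples.
#' @param alpha Significance gate on the BH-adjusted p-value.
#' @param seed Seed for within-stratum replicate pairing.
#' @return A list with `component` (smallest significant index or `NA`) and
#'   `table` (tibble: component, t, p, p_fdr).
#' @export
first_sex_separating_pc <- function(pca, metadata, pairing_keys,
                                    alpha = 0.05, seed = 1L) {
  stopifnot(inherits(pca, "pca_result"))
  design <- build_pairing(metadata, pairing_keys, seed = seed)
  if (nrow(design$pairs) == 0) stop("no complete female/male pair under the pairing keys")
  scores <- pca$scores
  idx_f <- match(design$pairs$female, rownames(scores))
  idx_m <- match(design$pairs$male, rownames(scores))
  if (anyNA(idx_f) || anyNA(idx_m)) stop("paired samples missing from PCA scores")
  res <- map(seq_len(ncol(scores)), function(k) {
    d <- scores[idx_f, k] - scores[idx_m, k]
    tt <- paired_t_stat(matrix(d, nrow = 1))
    tibble(component = k, t = tt$t, p = tt$p)
  }) |> bind_rows()
  res$p_fdr <- bh_adjust(res$p)
  sig <- res$component[res$p_fdr < alpha]
  list(component = if (length(sig)) min(sig) else NA_integer_, table = res)
}
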