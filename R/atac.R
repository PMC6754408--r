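# Differential chromatin accessibility. The adjusted test assumes most OCRs
# are not differential, so the spread of female-male differences among OCRs of
# similar mean intensity estimates the null scale at that intensity; the scale
# is the window MAD converted to a normal-equivalent SD (x 1.4826), which a
# few genuinely differential OCRs cannot distort.

#' Intensity-windowed MAD-adjusted differential accessibility test
#'
#' For each OCR i with overall mean log2 intensity m_i, the window holds all
#' other OCRs whose mean intensity lies within `window_width / 2` of m_i (the
#' focal OCR itself is excluded from the scale estimate). With d_j the
#' female-male difference of mean log2 accessibility of OCR j, the null scale
#' is `sigma_i = 1.4826 * MAD({d_j})`, the statistic `z_i = d_i / sigma_i`, and
#' the two-sided p comes from the standard normal. Windows smaller than
#' `min_window` are expanded symmetrically (in intensity rank) to the nearest
#' `min_window` OCRs and flagged; a zero window MAD falls back to the global
#' MAD with a flag; a zero global MAD is an error.
#'
#' @param ocr An [ocr_table()], log2 scale.
#' @param metadata Sample metadata with `sample_id` and `sex`.
#' @param window_width Full window width in log2 intensity units ("one unit
#'   window after log2" = 1.0, i.e. +/- 0.5 around the focal intensity);
#'   set 2.0 for the full-width +/- 1.0 interpretation.
#' @param min_window Minimum OCR count per window.
#' @return A `do_result`: list with `table` (tibble: ocr_id, annotation_class,
#'   associated_gene, mean_f, mean_m, log2fc, mean_intensity, window_size,
#'   sigma, z, p, p_fdr, window_expanded, mad_fallback).
#' @export
mad_adjusted_test <- function(ocr, metadata, window_width = 1.0,
                              min_window = 50) {
  stopifnot(inherits(ocr, "ocr_table"))
  metadata <- validate_metadata(metadata)
  n_ocr <- nrow(ocr$values)
  if (n_ocr < min_window) stop("fewer OCRs than min_window")
  ids_f <- metadata$sample_id[metadata$sex == "F"]
  ids_m <- metadata$sample_id[metadata$sex == "M"]
  if (!length(ids_f) || !length(ids_m)) stop("both sexes must be present")
  vf <- ocr$values[, match(ids_f, colnames(ocr$values)), drop = FALSE]
  vm <- ocr$values[, match(ids_m, colnames(ocr$values)), drop = FALSE]
  mean_f <- rowMeans(vf)
  mean_m <- rowMeans(vm)
  d <- mean_f - mean_m
  m <- rowMeans(cbind(vf, vm))

  ord <- order(m)
  m_sorted <- m[ord]
  d_sorted <- d[ord]
  half <- window_width / 2
  lo <- findInterval(m_sorted - half, m_sorted, left.open = TRUE) + 1L
  hi <- findInterval(m_sorted + half, m_sorted)
  global_mad <- mad(d, constant = 1.4826)
  if (global_mad == 0) stop("global MAD of female-male differences is zero")

  sigma_s <- numeric(n_ocr)
  wsize_s <- integer(n_ocr)
  expanded_s <- logical(n_ocr)
  fallback_s <- logical(n_ocr)
  for (r in seq_len(n_ocr)) {
    a <- lo[r]; b <- hi[r]
    if (b - a < min_window) { # window excl. focal OCR smaller than min_window
      # grow symmetrically in intensity rank to the nearest min_window OCRs
      while (b - a < min_window && (a > 1L || b < n_ocr)) {
        if (a > 1L) a <- a - 1L
        if (b - a < min_window && b < n_ocr) b <- b + 1L
      }
      expanded_s[r] <- TRUE
    }
    idx <- a:b
    idx <- idx[idx != r]
    s <- 1.4826 * median(abs(d_sorted[idx] - median(d_sorted[idx])))
    if (s == 0) {
      s <- global_mad
      fallback_s[r] <- TRUE
    }
    sigma_s[r] <- s
    wsize_s[r] <- length(idx)
  }
  sigma <- numeric(n_ocr); sigma[ord] <- sigma_s
  wsize <- integer(n_ocr); wsize[ord] <- wsize_s
  expanded <- logical(n_ocr); expanded[ord] <- expanded_s
  fallback <- logical(n_ocr); fallback[ord] <- fallback_s

  z <- d / sigma
  p <- 2 * pnorm(-abs(z))
  tbl <- tibble(ocr_id = ocr$ranges$ocr_id,
                annotation_class = ocr$ranges$annotation_class,
                associated_gene = ocr$ranges$associated_gene,
                mean_f = mean_f, mean_m = mean_m, log2fc = d,
                mean_intensity = m, window_size = wsize, sigma = sigma,
                z = z, p = p, p_fdr = bh_adjust(p),
                window_expanded = expanded, mad_fallback = fallback)
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), unname))
  structure(list(table = tbl, window_width = window_width,
                 min_window = min_window),
            class = "do_result")
}

#' @export
print.do_result <- function(x, ...) {
  cat(sprintf("<do_result> %d OCRs (window width %.2g, min window %d)\n",
              nrow(x$table), x$window_width, x$min_window))
  invisible(x)
}

#' Call differential OCRs
#'
#' An OCR is a DO iff `p_fdr < alpha` and `|log2fc| > log2(fc_fold)` (both
#' strict). Calls are partitioned by annotation class and by sex direction,
#' with unique associated genes counted per class.
#'
#' @param result A [mad_adjusted_test()] result.
#' @param alpha pFDR cutoff.
#' @param fc_fold Fold-change cutoff (linear scale).
#' @return A list with `table` (called OCRs), `by_class` (tibble: class,
#'   n_do, n_female, n_male, n_genes) and the criteria.
#' @export
call_dos <- function(result, alpha = 0.05, fc_fold = 2) {
  stopifnot(inherits(result, "do_result"))
  tbl <- result$table
  is_do <- tbl$p_fdr < alpha & abs(tbl$log2fc) > log2(fc_fold)
  hits <- tbl[is_do, ]
  hits$direction <- ifelse(hits$log2fc > 0, "female", "male")
  by_class <- hits |>
    group_by(annotation_class) |>
    summarise(n_do = n(),
              n_female = sum(direction == "female"),
              n_male = sum(direction == "male"),
              n_genes = dplyr::n_distinct(associated_gene[!is.na(associated_gene)]),
              .groups = "drop")
  list(table = hits, by_class = by_class, alpha = alpha, fc_fold = fc_fold)
}

#' Gene-body accessibility fold-change comparison
#'
#' Aggregates gene-body OCR female-male log2 fold changes per gene (mean over
#' the gene's OCRs), then Welch-tests the distribution of each SDEG list
#' against all remaining genes. Wrap the statistic with
#' [permutation_pvalue()] for a permutation p.
#'
#' @param result A [mad_adjusted_test()] result (or its table).
#' @param female_genes,male_genes SDEG gene symbol lists.
#' @return A list with `gene_fc` (tibble: gene, log2fc, group) and `tests`
#'   (tibble: comparison, n_set, n_background, t, df, p).
#' @export
genebody_fc_comparison <- function(result, female_genes, male_genes) {
  tbl <- if (inherits(result, "do_result")) result$table else as_tibble(result)
  gb <- tbl[tbl$annotation_class == "gene_body" & !is.na(tbl$associated_gene), ]
  if (!nrow(gb)) stop("no gene-body OCRs available")
  if (!length(female_genes) && !length(male_genes)) {
    stop("both SDEG lists are empty; nothing to compare")
  }
  gene_fc <- gb |>
    group_by(gene = associated_gene) |>
    summarise(log2fc = mean(log2fc), .groups = "drop") |>
    mutate(group = case_when(gene %in% female_genes ~ "female_sdeg",
                             gene %in% male_genes ~ "male_sdeg",
                             TRUE ~ "background"))
  bg <- gene_fc$log2fc[gene_fc$group == "background"]
  one_test <- function(set_name) {
    v <- gene_fc$log2fc[gene_fc$group == set_name]
    if (length(v) < 2) return(NULL)
    st <- unpaired_t_stat(matrix(v, 1), matrix(bg, 1))
    tibble(comparison = paste0(set_name, "_vs_background"),
           n_set = length(v), n_background = length(bg),
           t = st$t, df = st$df, p = st$p)
  }
  tests <- bind_rows(one_test("female_sdeg"), one_test("male_sdeg"))
  if (is.null(tests) || !nrow(tests)) stop("SDEG lists have fewer than 2 gene-body genes")
  list(gene_fc = gene_fc, tests = tests)
}
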