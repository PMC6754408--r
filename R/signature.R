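# Fold-change distribution analyses around gene signatures: expression
# filtering of signature genes, two-sample shift tests (signature vs
# background), per-module one-sample tests, and the paired comparison of
# stimulation fold changes between sexes.
#
# Genes are the unit of inference here, as in the source analyses; inter-gene
# correlation makes the analytic p anti-conservative, which is why a
# gene-label permutation p can be co-reported via permutation_pvalue().

#' Compute a named fold-change vector
#'
#' Per-gene log2 fold change between two sample groups (difference of group
#' means on the log2 scale).
#'
#' @param x An [expr_matrix()], log2 scale.
#' @param group_a,group_b Sample ids; the fold change is A - B.
#' @param contrast Label carried on the result.
#' @return Tibble with `gene_id`, `log2fc` and attribute `contrast`.
#' @export
fold_change_vector <- function(x, group_a, group_b, contrast = "A-B") {
  stopifnot(inherits(x, "expr_matrix"))
  ia <- match(group_a, colnames(x$values))
  ib <- match(group_b, colnames(x$values))
  if (anyNA(ia) || anyNA(ib)) stop("group samples missing from expression matrix")
  out <- tibble(gene_id = x$genes$gene_id,
                log2fc = rowMeans(x$values[, ia, drop = FALSE]) -
                  rowMeans(x$values[, ib, drop = FALSE]))
  attr(out, "contrast") <- contrast
  out
}

#' Filter signature genes by expression
#'
#' Keeps the signature genes present in the matrix whose log2 expression
#' exceeds `threshold` in at least `min_samples` samples; everything else goes
#' to the exclusion report.
#'
#' @param signature Character vector of gene ids.
#' @param x An [expr_matrix()], log2 scale.
#' @param threshold Noise threshold (log2).
#' @param min_samples Minimum samples above threshold (default 3).
#' @return A list with `kept` (character) and `excluded` (tibble: gene_id,
#'   reason).
#' @export
filter_signature_genes <- function(signature, x, threshold, min_samples = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  present <- signature %in% x$genes$gene_id
  excluded <- tibble(gene_id = signature[!present], reason = "absent")
  sig <- signature[present]
  idx <- match(sig, x$genes$gene_id)
  ok <- rowSums(x$values[idx, , drop = FALSE] > threshold) >= min_samples
  excluded <- bind_rows(excluded,
                        tibble(gene_id = sig[!ok], reason = "below_threshold"))
  list(kept = sig[ok], excluded = excluded)
}

#' Two-sample shift test of a signature's fold changes
#'
#' Welch two-sample two-sided t-test comparing the fold-change distribution of
#' the signature genes against the background (by default, all other genes in
#' the fold-change vector). Use [permutation_pvalue()] with a gene-label
#' shuffle design for a permutation p.
#'
#' @param fc A [fold_change_vector()] tibble.
#' @param signature Character vector of signature gene ids.
#' @param background Character vector of background gene ids; defaults to the
#'   complement of the signature.
#' @return Tibble with one row: n_signature, n_background, mean_signature,
#'   mean_background, t, df, p.
#' @export
shift_test_two_sample <- function(fc, signature, background = NULL) {
  sig_fc <- fc$log2fc[fc$gene_id %in% signature]
  bg_ids <- background %||% setdiff(fc$gene_id, signature)
  bg_fc <- fc$log2fc[fc$gene_id %in% bg_ids]
  if (length(sig_fc) < 2 || length(bg_fc) < 2) stop("both groups need >= 2 genes")
  st <- unpaired_t_stat(matrix(sig_fc, 1), matrix(bg_fc, 1))
  tibble(n_signature = length(sig_fc), n_background = length(bg_fc),
         mean_signature = mean(sig_fc), mean_background = mean(bg_fc),
         t = st$t, df = st$df, p = st$p)
}

#' Per-module one-sample shift tests
#'
#' One-sample two-sided t-test of each module's fold changes against zero,
#' BH-adjusted across modules, flagged at `p_fdr < alpha`.
#'
#' @param fc A [fold_change_vector()] tibble.
#' @param modules Named list mapping module label to gene ids (modules must be
#'   disjoint), or a two-column data frame (gene_id, module).
#' @param alpha Flag threshold on the adjusted p.
#' @return Tibble with module, n, mean_fc, t, df, p, p_fdr, significant.
#' @export
module_shift_tests <- function(fc, modules, alpha = 0.05) {
  if (is.data.frame(modules)) {
    modules <- split(modules$gene_id, modules$module)
  }
  all_genes <- unlist(modules)
  if (anyDuplicated(all_genes)) stop("modules must be disjoint")
  rows <- imap(modules, function(ids, nm) {
    v <- fc$log2fc[fc$gene_id %in% ids]
    if (length(v) < 2) stop("module '", nm, "' has fewer than 2 genes in the fold-change vector")
    st <- paired_t_stat(matrix(v, 1))
    tibble(module = nm, n = length(v), mean_fc = mean(v),
           t = st$t, df = st$df, p = st$p)
  }) |> bind_rows()
  rows$p_fdr <- bh_adjust(rows$p)
  rows$significant <- rows$p_fdr < alpha
  rows
}

#' Paired comparison of stimulation fold changes between sexes
#'
#' For each gene of the set, computes the stimulated-vs-unstimulated log2 fold
#' change within each sex (`FC_F`, `FC_M`) and applies a paired two-sided
#' t-test across genes to `FC_F - FC_M`.
#'
#' @param x An [expr_matrix()], log2 scale, containing stimulated and
#'   unstimulated samples of both sexes.
#' @param metadata Sample metadata with `sex` and `stimulation`.
#' @param gene_set Gene ids over which to test (e.g. IFN-upregulated genes).
#' @param unstim_label Value of `stimulation` marking unstimulated samples.
#' @return A list with `table` (tibble: gene_id, fc_f, fc_m, diff) and `test`
#'   (tibble: n, mean_diff, t, df, p).
#' @export
paired_fc_comparison <- function(x, metadata, gene_set, unstim_label = "none") {
  stopifnot(inherits(x, "expr_matrix"))
  metadata <- validate_metadata(metadata)
  grp <- function(sex, stim) {
    metadata$sample_id[metadata$sex == sex &
                         (metadata$stimulation == unstim_label) == stim]
  }
  ids <- list(f_un = grp("F", TRUE), f_st = grp("F", FALSE),
              m_un = grp("M", TRUE), m_st = grp("M", FALSE))
  if (any(lengths(ids) == 0)) stop("need stimulated and unstimulated samples for both sexes")
  idx <- match(intersect(gene_set, x$genes$gene_id), x$genes$gene_id)
  if (length(idx) < 2) stop("fewer than 2 genes of the set are in the matrix")
  mean_of <- function(sample_ids) {
    rowMeans(x$values[idx, match(sample_ids, colnames(x$values)), drop = FALSE])
  }
  fc_f <- mean_of(ids$f_st) - mean_of(ids$f_un)
  fc_m <- mean_of(ids$m_st) - mean_of(ids$m_un)
  d <- fc_f - fc_m
  st <- paired_t_stat(matrix(d, 1))
  list(table = tibble(gene_id = x$genes$gene_id[idx], fc_f = fc_f,
                      fc_m = fc_m, diff = d),
       test = tibble(n = length(d), mean_diff = mean(d),
                     t = st$t, df = st$df, p = st$p))
}
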