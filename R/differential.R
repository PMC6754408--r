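# Sex-biased differential expression machinery: pairing construction,
# vectorized paired/unpaired t-tests, BH adjustment, the two-criterion
# (pFDR + fold change) gene caller, and the sex x tissue two-way ANOVA.

#' Build a female/male paired design
#'
#' Within each stratum defined by the blocking keys, female and male samples
#' are paired; when several replicates exist the matching is a uniform random
#' permutation driven by `seed`. Surplus samples of either sex, and strata
#' lacking one sex entirely, are reported unpaired and excluded.
#'
#' @param metadata Sample metadata (`sample_id`, `sex`, blocking keys).
#' @param blocking_keys Metadata columns shared by both members of a pair
#'   (e.g. `c("cell_type", "dataset", "age_group")`).
#' @param seed Seed for within-stratum matching.
#' @return A `paired_design`: list with `pairs` (tibble: female, male,
#'   stratum), `blocking_keys`, `seed` and `unpaired` (tibble).
#' @export
build_pairing <- function(metadata, blocking_keys, seed = 1L) {
  metadata <- validate_metadata(metadata)
  missing_keys <- setdiff(blocking_keys, names(metadata))
  if (length(missing_keys)) stop("metadata lacks blocking key(s): ",
                                 paste(missing_keys, collapse = ", "))
  strata <- do.call(paste, c(metadata[blocking_keys], sep = "|"))
  pairs <- list()
  unpaired <- list()
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      f <- metadata$sample_id[idx][metadata$sex[idx] == "F"]
      m <- metadata$sample_id[idx][metadata$sex[idx] == "M"]
      f <- if (length(f) > 1) sample(f) else f
      m <- if (length(m) > 1) sample(m) else m
      k <- min(length(f), length(m))
      if (k > 0) {
        pairs[[length(pairs) + 1]] <- tibble(female = f[seq_len(k)],
                                             male = m[seq_len(k)], stratum = s)
      }
      extra <- c(if (length(f) > k) f[(k + 1):length(f)],
                 if (length(m) > k) m[(k + 1):length(m)])
      if (length(extra)) {
        unpaired[[length(unpaired) + 1]] <- tibble(sample_id = extra, stratum = s)
      }
    }
  })
  structure(list(
    pairs = if (length(pairs)) bind_rows(pairs) else
      tibble(female = character(), male = character(), stratum = character()),
    blocking_keys = blocking_keys, seed = as.integer(seed),
    unpaired = if (length(unpaired)) bind_rows(unpaired) else
      tibble(sample_id = character(), stratum = character())
  ), class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design> %d pairs (keys: %s), %d unpaired\n",
              nrow(x$pairs), paste(x$blocking_keys, collapse = ", "),
              nrow(x$unpaired)))
  invisible(x)
}

# Row-wise paired t on a genes x pairs matrix of within-pair differences.
# Zero difference variance gives t = 0, p = 1, degenerate = TRUE: FDR vectors
# downstream stay complete instead of propagating NaN.
paired_t_stat <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  degenerate <- s == 0
  t_stat <- ifelse(degenerate, 0, m / (s / sqrt(n)))
  p <- ifelse(degenerate, 1, 2 * pt(-abs(t_stat), df = n - 1))
  list(t = t_stat, p = p, df = n - 1, degenerate = degenerate)
}

#' Paired t-test per gene
#'
#' Classical two-sided paired t-test on within-pair (female - male) log2
#' differences; the fold change is the mean difference, i.e. the difference of
#' group means on the log2 scale.
#'
#' @param x An [expr_matrix()], log2 scale.
#' @param design A [build_pairing()] result with at least 2 pairs.
#' @return A `de_result`: list with `table` (tibble: gene_id, mean_f, mean_m,
#'   log2fc, t, df, p, p_fdr, degenerate), `method` and `n`.
#' @export
paired_ttest <- function(x, design) {
  stopifnot(inherits(x, "expr_matrix"), inherits(design, "paired_design"))
  if (nrow(design$pairs) < 2) stop("need at least 2 pairs")
  idx_f <- match(design$pairs$female, colnames(x$values))
  idx_m <- match(design$pairs$male, colnames(x$values))
  if (anyNA(idx_f) || anyNA(idx_m)) stop("pair members missing from expression matrix")
  vf <- x$values[, idx_f, drop = FALSE]
  vm <- x$values[, idx_m, drop = FALSE]
  st <- paired_t_stat(vf - vm)
  tbl <- tibble(gene_id = x$genes$gene_id,
                mean_f = rowMeans(vf), mean_m = rowMeans(vm),
                log2fc = rowMeans(vf - vm),
                t = st$t, df = st$df, p = st$p,
                p_fdr = bh_adjust(st$p), degenerate = st$degenerate)
  new_de_result(tbl, method = "paired_t", n = nrow(design$pairs))
}

#' Unpaired two-sample t-test per gene
#'
#' Two-sided two-sample t-test (Welch by default); the fold change is
#' `mean(group A) - mean(group B)` on the log2 scale.
#'
#' @param x An [expr_matrix()], log2 scale.
#' @param group_a,group_b Sample ids of the two groups (each of size >= 2);
#'   fold changes are reported A - B.
#' @param equal_var Use the pooled-variance test instead of Welch.
#' @return A `de_result` (see [paired_ttest()]); `mean_f`/`mean_m` hold the
#'   A/B group means.
#' @export
unpaired_ttest <- function(x, group_a, group_b, equal_var = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs >= 2 samples")
  ia <- match(group_a, colnames(x$values))
  ib <- match(group_b, colnames(x$values))
  if (anyNA(ia) || anyNA(ib)) stop("group samples missing from expression matrix")
  va <- x$values[, ia, drop = FALSE]
  vb <- x$values[, ib, drop = FALSE]
  st <- unpaired_t_stat(va, vb, equal_var = equal_var)
  tbl <- tibble(gene_id = x$genes$gene_id,
                mean_f = rowMeans(va), mean_m = rowMeans(vb),
                log2fc = rowMeans(va) - rowMeans(vb),
                t = st$t, df = st$df, p = st$p,
                p_fdr = bh_adjust(st$p), degenerate = st$degenerate)
  new_de_result(tbl, method = if (equal_var) "pooled_t" else "welch_t",
                n = c(length(group_a), length(group_b)))
}

unpaired_t_stat <- function(va, vb, equal_var = FALSE) {
  n1 <- ncol(va); n2 <- ncol(vb)
  m1 <- rowMeans(va); m2 <- rowMeans(vb)
  v1 <- rowSums((va - m1)^2) / (n1 - 1)
  v2 <- rowSums((vb - m2)^2) / (n2 - 1)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  zero_se <- se == 0
  diff <- m1 - m2
  degenerate <- zero_se
  t_stat <- ifelse(zero_se, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
  p <- ifelse(zero_se, ifelse(diff == 0, 1, .Machine$double.xmin),
              2 * pt(-abs(t_stat), df = pmax(df, 1e-12)))
  df[zero_se] <- NA_real_
  list(t = t_stat, p = p, df = df, degenerate = degenerate)
}

new_de_result <- function(table, method, n) {
  # rowwise kernels can leave gene names on numeric columns; keep columns bare
  table <- dplyr::mutate(table, dplyr::across(dplyr::everything(), unname))
  structure(list(table = table, method = method, n = n), class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s, %d genes, n = %s\n", x$method,
              nrow(x$table), paste(x$n, collapse = "/")))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in p and capped at 1, returned in the
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (pFDR).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call sexually differentially expressed genes
#'
#' A gene is called iff `p_fdr < alpha` and `|log2fc| > log2(fc_fold)` (both
#' strict), then partitioned by fold-change sign into female-higher
#' (`log2fc > 0`) and male-higher lists.
#'
#' @param de A `de_result`.
#' @param alpha pFDR cutoff (0.2 for the baseline criteria; 0.05 for the more
#'   stringent IFN analysis).
#' @param fc_fold Fold-change cutoff on the linear scale (1.5 baseline; 2 for
#'   the IFN analysis).
#' @return A list with `female`, `male` (gene id vectors), `table` (called
#'   genes) and the criteria used.
#' @export
call_sdegs <- function(de, alpha = 0.2, fc_fold = 1.5) {
  stopifnot(inherits(de, "de_result"))
  tbl <- de$table
  called <- tbl$p_fdr < alpha & abs(tbl$log2fc) > log2(fc_fold)
  hit <- tbl[called, ]
  list(female = hit$gene_id[hit$log2fc > 0],
       male = hit$gene_id[hit$log2fc < 0],
       table = hit, alpha = alpha, fc_fold = fc_fold)
}

#' Two-way ANOVA per gene (sex x tissue)
#'
#' Per-gene F-tests for the sex effect, the tissue effect and their
#' interaction from a two-factor linear model with interaction, Type III sums
#' of squares with sum-to-zero contrasts by default (Type II via `type = 2`).
#' Per-tissue log2 fold changes (female - male) come from tissue-stratified
#' group means. Unbalanced designs are allowed; an empty (sex, tissue) cell is
#' an error.
#'
#' @param x An [expr_matrix()], log2 scale.
#' @param metadata Sample metadata with `sex` and the tissue column.
#' @param tissue_col Metadata column holding the tissue factor.
#' @param type Sums-of-squares type, 3 (default) or 2.
#' @return An `anova_result`: list with `table` (tibble: gene_id, p_sex,
#'   p_tissue, p_interaction, their `p_fdr_*`, and one `fc_<tissue>` column
#'   per tissue), `tissues` and `type`.
#' @export
two_way_anova <- function(x, metadata, tissue_col = "tissue", type = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  metadata <- validate_metadata(metadata)
  idx <- match(metadata$sample_id, colnames(x$values))
  if (anyNA(idx)) stop("metadata samples missing from expression matrix")
  Y <- x$values[, idx, drop = FALSE]
  sex <- factor(metadata$sex, levels = c("F", "M"))
  tissue <- factor(metadata[[tissue_col]])
  tissues <- levels(tissue)
  cells <- table(sex, tissue)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty (sex, tissue) cell(s): ",
         paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  n <- ncol(Y)
  rss <- function(X) {
    qr_x <- qr(X)
    H_resid <- diag(n) - tcrossprod(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE])
    rowSums((Y %*% H_resid) * (Y %*% H_resid))
  }
  one <- matrix(1, n, 1)
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  if (length(tissues) >= 2) {
    X_full <- model.matrix(~ sex * tissue)
    X_sex <- model.matrix(~ sex)
    X_tissue <- model.matrix(~ tissue)
    X_main <- model.matrix(~ sex + tissue)
    asgn <- attr(X_full, "assign") # 0 intercept, 1 sex, 2 tissue, 3 interaction
    rss_full <- rss(X_full)
    df_res <- n - qr(X_full)$rank
    if (df_res < 1) stop("no residual degrees of freedom")
    test_term <- function(term_code) {
      if (type == 3) {
        X_red <- X_full[, asgn != term_code, drop = FALSE]
        X_big <- X_full
        rss_big <- rss_full
      } else {
        X_big <- switch(as.character(term_code),
                        "1" = X_main, "2" = X_main, "3" = X_full)
        X_red <- switch(as.character(term_code),
                        "1" = X_tissue, "2" = X_sex, "3" = X_main)
        rss_big <- rss(X_big)
      }
      df_term <- qr(X_big)$rank - qr(X_red)$rank
      f_stat <- ((rss(X_red) - rss_big) / df_term) / (rss_full / df_res)
      f_stat <- pmax(f_stat, 0)
      stats::pf(f_stat, df_term, df_res, lower.tail = FALSE)
    }
    p_sex <- test_term(1)
    p_tissue <- test_term(2)
    p_int <- test_term(3)
  } else {
    # single tissue: only the sex effect is testable
    X_full <- model.matrix(~ sex)
    rss_full <- rss(X_full)
    df_res <- n - qr(X_full)$rank
    f_stat <- ((rss(one) - rss_full) / 1) / (rss_full / df_res)
    p_sex <- stats::pf(pmax(f_stat, 0), 1, df_res, lower.tail = FALSE)
    p_tissue <- rep(NA_real_, nrow(Y))
    p_int <- rep(NA_real_, nrow(Y))
  }
  tbl <- tibble(gene_id = x$genes$gene_id,
                p_sex = p_sex, p_tissue = p_tissue, p_interaction = p_int,
                p_fdr_sex = bh_adjust(p_sex),
                p_fdr_tissue = if (all(is.na(p_tissue))) p_tissue else bh_adjust(p_tissue),
                p_fdr_interaction = if (all(is.na(p_int))) p_int else bh_adjust(p_int))
  for (tis in tissues) {
    sel_f <- which(tissue == tis & sex == "F")
    sel_m <- which(tissue == tis & sex == "M")
    tbl[[paste0("fc_", tis)]] <-
      rowMeans(Y[, sel_f, drop = FALSE]) - rowMeans(Y[, sel_m, drop = FALSE])
  }
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), unname))
  structure(list(table = tbl, tissues = tissues, type = type,
                 tissue_col = tissue_col),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %d genes, tissues: %s (type %s SS)\n",
              nrow(x$table), paste(x$tissues, collapse = ", "), x$type))
  invisible(x)
}

#' Call sex-effect and sex-by-tissue interaction genes
#'
#' A sex-effect gene has interaction-free evidence in every tissue:
#' `p_fdr_sex < alpha` and `|log2fc| > log2(fc_fold)` with a consistent sign
#' in all tissues. An interaction gene for tissue T has
#' `p_fdr_interaction < alpha`, `|log2fc in T| > log2(fc_fold)` and passes the
#' expression gate in T: expression above `expr_threshold` in all female or
#' all male samples of T (`gate = "all_one_sex"`, default) or in at least two
#' samples of T (`gate = "two_samples"`).
#'
#' @param anova An [two_way_anova()] result.
#' @param x The [expr_matrix()] the ANOVA used.
#' @param metadata Its metadata.
#' @param alpha pFDR cutoff.
#' @param fc_fold Fold-change cutoff (linear scale).
#' @param expr_threshold Log2 expression gate for interaction genes.
#' @param gate Expression-gate rule (see above).
#' @return A list with `sex_effect` (tibble: gene_id, direction) and
#'   `interaction` (named list per tissue of tibbles: gene_id, direction).
#' @export
call_tissue_genes <- function(anova, x, metadata, alpha = 0.2, fc_fold = 1.5,
                              expr_threshold = 6,
                              gate = c("all_one_sex", "two_samples")) {
  gate <- match.arg(gate)
  stopifnot(inherits(anova, "anova_result"), inherits(x, "expr_matrix"))
  metadata <- validate_metadata(metadata)
  tbl <- anova$table
  fc_cols <- paste0("fc_", anova$tissues)
  fc <- as.matrix(tbl[fc_cols])
  cut <- log2(fc_fold)
  all_big <- rowSums(abs(fc) > cut) == length(anova$tissues)
  consistent <- abs(rowSums(sign(fc))) == length(anova$tissues)
  sex_hit <- tbl$p_fdr_sex < alpha & all_big & consistent
  sex_effect <- tibble(gene_id = tbl$gene_id[sex_hit],
                       direction = ifelse(unname(fc[sex_hit, 1]) > 0,
                                          "female", "male"))
  tissue_fac <- metadata[[anova$tissue_col]]
  interaction <- list()
  for (k in seq_along(anova$tissues)) {
    tis <- anova$tissues[k]
    ids_f <- metadata$sample_id[tissue_fac == tis & metadata$sex == "F"]
    ids_m <- metadata$sample_id[tissue_fac == tis & metadata$sex == "M"]
    vals_t <- x$values[, c(ids_f, ids_m), drop = FALSE]
    expressed <- switch(gate,
      all_one_sex =
        rowSums(x$values[, ids_f, drop = FALSE] > expr_threshold) == length(ids_f) |
        rowSums(x$values[, ids_m, drop = FALSE] > expr_threshold) == length(ids_m),
      two_samples = rowSums(vals_t > expr_threshold) >= 2)
    hit <- !is.na(tbl$p_fdr_interaction) & tbl$p_fdr_interaction < alpha &
      abs(fc[, k]) > cut & expressed
    interaction[[tis]] <- tibble(gene_id = tbl$gene_id[hit],
                                 direction = ifelse(unname(fc[hit, k]) > 0,
                                                    "female", "male"))
  }
  list(sex_effect = sex_effect, interaction = interaction,
       alpha = alpha, fc_fold = fc_fold, expr_threshold = expr_threshold,
       gate = gate)
}
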