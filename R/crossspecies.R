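# Human-mouse comparison of sexually differential expression: the microarray
# gene-level expression filter, ortholog mapping with expression gating, and
# direction-consistency testing at fold-change thresholds.

#' Gene-level low-expression filter (array-style)
#'
#' A gene is flagged for removal iff it is expressed below the per-sample 10%
#' expression quantile in more than `fraction` of the males AND more than
#' `fraction` of the females (the quantile is computed within each sample).
#'
#' @param x An [expr_matrix()].
#' @param metadata Sample metadata with `sample_id` and `sex`.
#' @param quantile_cut Per-sample expression quantile (default 0.10).
#' @param fraction Fraction of samples of a sex that must be below the
#'   quantile (default 2/3); strict `>`.
#' @return A list with `kept` and `removed` gene id vectors.
#' @export
immvar_gene_filter <- function(x, metadata, quantile_cut = 0.10,
                               fraction = 2 / 3) {
  stopifnot(inherits(x, "expr_matrix"))
  metadata <- validate_metadata(metadata)
  idx <- match(metadata$sample_id, colnames(x$values))
  if (anyNA(idx)) stop("metadata samples missing from expression matrix")
  vals <- x$values[, idx, drop = FALSE]
  cuts <- apply(vals, 2, quantile, probs = quantile_cut, names = FALSE)
  below <- sweep(vals, 2, cuts, "<")
  is_m <- metadata$sex == "M"
  is_f <- metadata$sex == "F"
  n_m <- sum(is_m); n_f <- sum(is_f)
  if (n_m == 0 || n_f == 0) stop("both sexes are required")
  low_m <- rowSums(below[, is_m, drop = FALSE]) > fraction * n_m
  low_f <- rowSums(below[, is_f, drop = FALSE]) > fraction * n_f
  removed <- low_m & low_f
  list(kept = x$genes$gene_id[!removed], removed = x$genes$gene_id[removed])
}

#' Join human DE results to mouse fold changes through an ortholog map
#'
#' Keeps human genes with `qfdr < q_cut` that have a mouse ortholog whose
#' expression exceeds 0 in at least `min_expressed` mouse samples; returns the
#' joined fold-change table and an exclusion report. Many-to-many ortholog
#' rows are resolved to the first (highest-confidence) pairing per human
#' symbol; a mouse symbol claimed by two human symbols keeps the first and the
#' rest are dropped and reported.
#'
#' @param human Tibble with columns `symbol`, `log2fc`, `qfdr`.
#' @param map Tibble with columns `human_symbol`, `mouse_symbol`, ordered by
#'   decreasing mapping confidence.
#' @param mouse_fc Tibble with columns `symbol`, `log2fc` (mouse, F - M).
#' @param mouse_expr An [expr_matrix()] of mouse expression, or `NULL` to skip
#'   the expression gate.
#' @param q_cut Human significance cutoff.
#' @param min_expressed Minimum mouse samples with expression > 0.
#' @return A list with `joined` (tibble: human_symbol, mouse_symbol,
#'   human_log2fc, mouse_log2fc) and `excluded` (tibble: symbol, reason).
#' @export
map_orthologs <- function(human, map, mouse_fc, mouse_expr = NULL,
                          q_cut = 0.05, min_expressed = 3) {
  human <- as_tibble(human)
  map <- as_tibble(map)
  mouse_fc <- as_tibble(mouse_fc)
  excl <- list()
  de <- human[human$qfdr < q_cut, ]
  excl$not_de <- tibble(symbol = setdiff(human$symbol, de$symbol),
                        reason = "not_significant")
  map <- map[!duplicated(map$human_symbol), ]
  dup_mouse <- duplicated(map$mouse_symbol)
  if (any(dup_mouse)) {
    excl$ambiguous <- tibble(symbol = map$human_symbol[dup_mouse],
                             reason = "ambiguous_ortholog")
    map <- map[!dup_mouse, ]
  }
  j <- left_join(de, map, by = c(symbol = "human_symbol"))
  no_orth <- is.na(j$mouse_symbol)
  excl$unmapped <- tibble(symbol = j$symbol[no_orth], reason = "no_ortholog")
  j <- j[!no_orth, ]
  if (!is.null(mouse_expr)) {
    stopifnot(inherits(mouse_expr, "expr_matrix"))
    n_expressed <- rowSums(mouse_expr$values > 0)
    names(n_expressed) <- mouse_expr$genes$gene_id
    ok <- !is.na(n_expressed[j$mouse_symbol]) &
      n_expressed[j$mouse_symbol] >= min_expressed
    excl$unexpressed <- tibble(symbol = j$symbol[!ok], reason = "mouse_unexpressed")
    j <- j[ok, ]
  }
  j <- left_join(j, rename(mouse_fc, mouse_symbol = symbol,
                           mouse_log2fc = log2fc),
                 by = "mouse_symbol")
  no_fc <- is.na(j$mouse_log2fc)
  excl$no_mouse_fc <- tibble(symbol = j$symbol[no_fc], reason = "no_mouse_fc")
  j <- j[!no_fc, ]
  if (!nrow(j)) stop("empty join: no human DE gene survives mapping and gating")
  list(joined = tibble(human_symbol = j$symbol, mouse_symbol = j$mouse_symbol,
                       human_log2fc = j$log2fc, mouse_log2fc = j$mouse_log2fc),
       excluded = bind_rows(excl))
}

#' Human-mouse fold-change direction-consistency test
#'
#' At each threshold t, counts the human genes with the side's direction and
#' `|log2fc| > t` (strict), the mouse genes likewise, and their overlap, and
#' computes an upper-tail hypergeometric p with the joined universe as the
#' population and the mouse side-direction genes as successes. A binomial sign
#' test (P(overlap | each human gene concordant with prob = mouse fraction))
#' is available via `method = "binomial"`.
#'
#' @param joined The `joined` table from [map_orthologs()].
#' @param thresholds Log2 fold-change thresholds.
#' @param side `"female"` (positive fold changes) or `"male"`.
#' @param method `"hypergeometric"` (default) or `"binomial"`.
#' @return Tibble with threshold, n_human, n_mouse, n_overlap, n_universe, p.
#' @export
direction_consistency_test <- function(joined, thresholds = c(0, 0.1, 0.2),
                                       side = c("female", "male"),
                                       method = c("hypergeometric", "binomial")) {
  side <- match.arg(side)
  method <- match.arg(method)
  joined <- as_tibble(joined)
  if (!nrow(joined)) stop("joined table is empty")
  sgn <- if (side == "female") 1 else -1
  map(thresholds, function(t) {
    h <- sgn * joined$human_log2fc > t
    m <- sgn * joined$mouse_log2fc > t
    n_h <- sum(h); n_m <- sum(m); n_o <- sum(h & m); n_u <- nrow(joined)
    p <- if (n_h == 0 || n_m == 0) {
      NA_real_
    } else if (method == "hypergeometric") {
      hypergeom_overlap(n_hits = n_h, set_size = n_m, overlap = n_o,
                        background_size = n_u)
    } else {
      stats::binom.test(n_o, n_h, p = n_m / n_u,
                        alternative = "greater")$p.value
    }
    tibble(threshold = t, n_human = n_h, n_mouse = n_m, n_overlap = n_o,
           n_universe = n_u, p = p)
  }) |> bind_rows()
}
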