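# Pre-ranked gene-set enrichment (weighted Kolmogorov-Smirnov walk with a
# random-gene-set null) and hypergeometric over-representation with a fixed
# background.

#' GSEA enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov walk down a ranked list: hits increment
#' the running sum by `|score|^p / sum(|score|^p over hits)`, misses decrement
#' it by `1 / (N - N_hits)`; the enrichment score is the signed maximum
#' deviation from zero, and the leading edge contains the set genes up to (for
#' positive ES) or from (negative ES) the extremum.
#'
#' @param genes Character vector, ranked best-to-worst (descending score).
#' @param scores Numeric scores aligned to `genes` (descending).
#' @param gene_set Character vector of set members.
#' @param p Weighting exponent (1 = classic weighted; 0 = unweighted KS).
#' @return A list with `es`, `running_sum` (length N) and `leading_edge`.
#' @export
enrichment_score <- function(genes, scores, gene_set, p = 1) {
  n <- length(genes)
  stopifnot(length(scores) == n)
  if (is.unsorted(rev(scores))) stop("scores must be sorted descending")
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set has no overlap with the ranked list")
  if (n_hit == n) stop("gene set covers the whole ranked list")
  w <- abs(scores)^p
  increments <- numeric(n)
  increments[hit] <- w[hit] / sum(w[hit])
  increments[!hit] <- -1 / (n - n_hit)
  running <- cumsum(increments)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
             else genes[i_max:n][hit[i_max:n]]
  list(es = es, running_sum = running, leading_edge = leading)
}

#' Pre-ranked GSEA
#'
#' Scores each gene set by [enrichment_score()] on a ranked list, builds a
#' per-set null from `B` random gene sets of identical size drawn from the
#' ranked universe, normalizes (NES = ES divided by the mean |null ES| of
#' matching sign), computes a matching-sign nominal p, and an FDR q by the
#' positive/negative pooling scheme of the original method (BH over nominal
#' p-values via `fdr = "BH"`).
#'
#' @param ranked Tibble/data frame with columns `gene` and `score`, or a named
#'   numeric vector. Sorted internally by score descending; ties keep input
#'   order (with a warning).
#' @param collection A [gene_sets()] object.
#' @param p Weighting exponent.
#' @param B Random sets per gene set (>= 100).
#' @param seed Integer seed.
#' @param min_size,max_size Set-size limits after restriction to the ranked
#'   universe; sets outside are excluded and reported.
#' @param fdr `"gsea"` (positive/negative pooled scheme) or `"BH"`.
#' @param q_cut Significance flag threshold on q.
#' @return A `gsea_result`: list with `table` (tibble: set, size, es, nes,
#'   p, q, significant, leading_edge list-column), `excluded` (tibble) and the
#'   parameters.
#' @export
gsea_preranked <- function(ranked, collection, p = 1, B = 1000, seed = 1L,
                           min_size = 15, max_size = 500,
                           fdr = c("gsea", "BH"), q_cut = 0.25) {
  fdr <- match.arg(fdr)
  if (B < 100) stop("B must be >= 100")
  stopifnot(inherits(collection, "gene_sets"))
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(gene = names(ranked), score = unname(ranked))
  }
  ranked <- as_tibble(ranked)
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) stop("duplicate genes in ranked list")
  ord <- order(ranked$score, decreasing = TRUE)
  if (anyDuplicated(ranked$score)) {
    warning("ties in the ranked statistic broken by input order")
  }
  genes <- ranked$gene[ord]
  scores <- ranked$score[ord]
  n <- length(genes)

  restricted <- lapply(collection$sets, function(s) intersect(s, genes))
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  excluded <- tibble(set = names(restricted)[!keep], size = sizes[!keep])
  restricted <- restricted[keep]
  sizes <- sizes[keep]

  w <- abs(scores)^p
  es_for_idx <- function(idx_hits) {
    increments <- rep(-1 / (n - length(idx_hits)), n)
    increments[idx_hits] <- w[idx_hits] / sum(w[idx_hits])
    running <- cumsum(increments)
    running[which.max(abs(running))]
  }

  rows <- with_seed(seed, {
    imap(restricted, function(set_genes, nm) {
      obs <- enrichment_score(genes, scores, set_genes, p = p)
      k <- length(set_genes)
      null_es <- vapply(seq_len(B), function(b) {
        es_for_idx(sample.int(n, k))
      }, numeric(1))
      same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nominal_p <- (1 + sum(abs(same_sign) >= abs(obs$es))) /
        (1 + length(same_sign))
      denom <- mean(abs(same_sign))
      nes <- if (length(same_sign) && denom > 0) obs$es / denom else NA_real_
      null_nes_pos <- null_es[null_es >= 0] / max(mean(null_es[null_es >= 0]), .Machine$double.eps)
      null_nes_neg <- -null_es[null_es < 0] / max(mean(-null_es[null_es < 0]), .Machine$double.eps)
      tibble(set = nm, size = k, es = obs$es, nes = nes, p = nominal_p,
             leading_edge = list(obs$leading_edge),
             null_nes = list(list(pos = null_nes_pos, neg = null_nes_neg)))
    }) |> bind_rows()
  })

  if (nrow(rows)) {
    if (fdr == "BH") {
      rows$q <- bh_adjust(rows$p)
    } else {
      # original-method scheme: for each set, compare the fraction of pooled
      # null NES (matching sign) at least as extreme as the set's NES with the
      # fraction of observed NES (matching sign) at least as extreme
      all_null_pos <- unlist(lapply(rows$null_nes, function(z) z$pos))
      all_null_neg <- unlist(lapply(rows$null_nes, function(z) z$neg))
      obs_nes <- rows$nes
      rows$q <- vapply(seq_len(nrow(rows)), function(i) {
        nes_i <- obs_nes[i]
        if (is.na(nes_i)) return(NA_real_)
        if (nes_i >= 0) {
          null_frac <- mean(all_null_pos >= nes_i)
          obs_frac <- mean(obs_nes[obs_nes >= 0] >= nes_i)
        } else {
          null_frac <- mean(all_null_neg >= -nes_i)
          obs_frac <- mean(obs_nes[obs_nes < 0] <= nes_i)
        }
        min(1, null_frac / max(obs_frac, .Machine$double.eps))
      }, numeric(1))
    }
    rows$significant <- !is.na(rows$q) & rows$q < q_cut
  }
  rows$null_nes <- NULL
  structure(list(table = rows, excluded = excluded,
                 params = list(p = p, B = B, seed = seed, min_size = min_size,
                               max_size = max_size, fdr = fdr, q_cut = q_cut)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d sets scored (%d excluded), %d significant at q < %.2g\n",
              nrow(x$table), nrow(x$excluded),
              sum(x$table$significant %||% logical(0)),
              x$params$q_cut))
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` for `X ~
#' Hypergeometric(background_size, set_size, n_hits)` -- the chance of seeing
#' at least the observed overlap between a hit list and a gene set drawn from
#' a fixed background.
#'
#' @param n_hits Number of genes in the hit list.
#' @param set_size Number of background genes in the set.
#' @param overlap Observed overlap.
#' @param background_size Background universe size (e.g. all genes above the
#'   noise threshold).
#' @return Upper-tail p-value.
#' @export
hypergeom_overlap <- function(n_hits, set_size, overlap, background_size) {
  if (set_size > background_size || n_hits > background_size) {
    warning("set or hit list larger than background; clamping")
    set_size <- min(set_size, background_size)
    n_hits <- min(n_hits, background_size)
  }
  if (overlap > min(n_hits, set_size)) stop("overlap exceeds min(|hits|, |set|)")
  phyper(overlap - 1, set_size, background_size - set_size, n_hits,
         lower.tail = FALSE)
}
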