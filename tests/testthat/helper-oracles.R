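# Shared fixtures and independent brute-force oracles used across test files.
# The oracles deliberately avoid the package's internal code paths: they are
# straight transcriptions of the textbook definitions.

# ---- fixtures ---------------------------------------------------------------

# metadata for n_pairs female/male pairs blocked on a "pair" key
toy_pair_metadata <- function(n_pairs) {
  tibble::tibble(
    sample_id = c(sprintf("F%d", seq_len(n_pairs)),
                  sprintf("M%d", seq_len(n_pairs))),
    sex = rep(c("F", "M"), each = n_pairs),
    pair = rep(seq_len(n_pairs), 2)
  )
}

toy_design <- function(n_pairs) {
  build_pairing(toy_pair_metadata(n_pairs), "pair")
}

# expr_matrix holding one row per gene; f and m are genes x pairs matrices
toy_paired_expr <- function(f, m) {
  f <- rbind(f); m <- rbind(m)
  vals <- cbind(f, m)
  colnames(vals) <- c(sprintf("F%d", seq_len(ncol(f))),
                      sprintf("M%d", seq_len(ncol(m))))
  rownames(vals) <- sprintf("gene%d", seq_len(nrow(vals)))
  expr_matrix(vals, scale = "log2")
}

# a de_result-shaped object for exercising callers on synthetic tables
fake_de_result <- function(table) {
  structure(list(table = table, method = "paired_t", n = 6L),
            class = "de_result")
}

fake_do_result <- function(table, window_width = 1, min_window = 50) {
  structure(list(table = table, window_width = window_width,
                 min_window = min_window),
            class = "do_result")
}

# ---- oracles ----------------------------------------------------------------

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    val <- min(1, p[o[i]] * m / i)
    running_min <- min(running_min, val)
    adj[o[i]] <- running_min
  }
  adj
}

# upper-tail hypergeometric by direct summation of point probabilities
oracle_hyper <- function(n_hits, set_size, overlap, background_size) {
  ks <- overlap:min(n_hits, set_size)
  sum(choose(set_size, ks) * choose(background_size - set_size, n_hits - ks)) /
    choose(background_size, n_hits)
}

# GSEA running-sum walk as an explicit loop
oracle_es <- function(genes, scores, gene_set, p = 1) {
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  denom_hit <- sum(abs(scores[hit])^p)
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) running <- running + abs(scores[i])^p / denom_hit
    else running <- running - 1 / (n - nh)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# classic Tukey median polish (rows first), mirroring the published algorithm
oracle_medpolish <- function(x, max_iter = 10, tol = 1e-6) {
  z <- as.matrix(x)
  nr <- nrow(z); nc <- ncol(z)
  overall <- 0
  row_eff <- numeric(nr)
  col_eff <- numeric(nc)
  oldsum <- 0
  for (iter in seq_len(max_iter)) {
    rdelta <- apply(z, 1, median)
    z <- z - matrix(rdelta, nr, nc)
    row_eff <- row_eff + rdelta
    delta <- median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(z, 2, median)
    z <- z - matrix(cdelta, nr, nc, byrow = TRUE)
    col_eff <- col_eff + cdelta
    delta <- median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, row_effects = row_eff, col_effects = col_eff,
       residuals = z)
}

# quantile normalization by explicit rank averaging (no ties expected)
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col)])
}
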