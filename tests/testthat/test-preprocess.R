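test_that("floor_log_transform floors at 1 and log2-transforms", {
  vals <- matrix(c(0.5, 8, 1, 2), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  x <- expr_matrix(vals, scale = "linear")
  out <- floor_log_transform(x)
  expect_identical(out$scale, "log2")
  expect_equal(unname(out$values), matrix(c(0, 3, 0, 1), 2, 2))
  expect_error(floor_log_transform(expr_matrix(vals, scale = "log2")),
               "linear")
})

test_that("noise filter uses a strict threshold", {
  vals <- rbind(kept = c(rep(5.1, 6), rep(0, 6)),
                boundary = rep(5.0, 12))
  colnames(vals) <- sprintf("s%02d", 1:12)
  x <- expr_matrix(vals, scale = "log2")
  out <- noise_filter(x, threshold = 5, min_samples = 6)
  expect_identical(out$expr$genes$gene_id, "kept")
  expect_identical(out$dropped, "boundary")
})

test_that("noise filter matches brute force and commutes with reordering", {
  set.seed(51)
  vals <- matrix(runif(1000 * 8, 0, 10), 1000, 8,
                 dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%d", 1:8)))
  x <- expr_matrix(vals, scale = "log2")
  out <- noise_filter(x, threshold = 5, min_samples = 3)
  brute <- vapply(seq_len(nrow(vals)),
                  function(i) sum(vals[i, ] > 5) >= 3, logical(1))
  expect_identical(out$expr$genes$gene_id, rownames(vals)[brute])

  perm <- sample.int(1000)
  x2 <- expr_matrix(vals[perm, ], scale = "log2")
  out2 <- noise_filter(x2, threshold = 5, min_samples = 3)
  expect_setequal(out2$expr$genes$gene_id, out$expr$genes$gene_id)
})

test_that("zscore_normalize uses the sample-SD convention", {
  vals <- rbind(g1 = c(1, 2, 3))
  colnames(vals) <- c("a", "b", "c")
  out <- zscore_normalize(expr_matrix(vals, scale = "log2"))
  expect_equal(unname(out$values[1, ]), c(-1, 0, 1))

  const <- rbind(g1 = c(2, 2, 2))
  colnames(const) <- c("a", "b", "c")
  expect_error(zscore_normalize(expr_matrix(const, scale = "log2")), "g1")

  set.seed(52)
  r <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:6)))
  z <- zscore_normalize(expr_matrix(r, scale = "log2"))$values
  expect_equal(unname(rowMeans(z)), rep(0, 40), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 40), tolerance = 1e-9)
})

test_that("median-of-ratios size factors match the hand example", {
  counts <- cbind(s1 = c(2, 8, 4), s2 = c(4, 16, 8))
  rownames(counts) <- c("a", "b", "c")
  out <- median_of_ratios_normalize(expr_matrix(counts, scale = "counts"))
  expect_equal(unname(out$size_factors["s2"] / out$size_factors["s1"]), 2)
  expect_equal(out$expr$values[, 1], out$expr$values[, 2])
  expect_identical(out$expr$scale, "linear")

  single <- expr_matrix(cbind(s1 = c(2, 8, 4)), gene_ids = c("a", "b", "c"),
                        scale = "counts")
  out1 <- median_of_ratios_normalize(single)
  expect_equal(unname(out1$size_factors), 1)
  expect_equal(out1$expr$values, single$values)
})

test_that("median-of-ratios is permutation-equivariant and matches DESeq2", {
  set.seed(53)
  counts <- matrix(rnbinom(200 * 6, mu = 50, size = 3), 200, 6,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  x <- expr_matrix(counts, scale = "counts")
  sf <- median_of_ratios_normalize(x)$size_factors

  perm <- c(3, 1, 6, 2, 5, 4)
  sf_perm <- median_of_ratios_normalize(
    expr_matrix(counts[, perm], scale = "counts"))$size_factors
  expect_equal(unname(sf_perm), unname(sf[perm]))

  deseq_sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(sf), unname(deseq_sf), tolerance = 1e-10)
})

test_that("quantile normalization matches the hand example and is idempotent", {
  m <- cbind(a = c(1, 3, 5), b = c(2, 4, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  set.seed(54)
  r <- matrix(rnorm(60 * 5), 60, 5)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  sorted <- apply(q1, 2, sort)
  expect_equal(sorted[, 1], sorted[, 3], tolerance = 1e-12)
  expect_equal(q1, oracle_quantile_normalize(r), tolerance = 1e-12)
})

test_that("median polish recovers additive structure and matches the oracle", {
  add <- matrix(c(1, 3, 2, 4), 2, 2)
  fit <- median_polish(add)
  expect_equal(fit$residuals, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(fit$overall + outer(fit$row_effects, fit$col_effects, "+"),
               add, ignore_attr = TRUE)

  set.seed(55)
  x <- matrix(rnorm(24, 10, 3), 6, 4)
  fit <- median_polish(x, max_iter = 10, tol = 1e-6)
  recon <- fit$overall + outer(fit$row_effects, fit$col_effects, "+") +
    fit$residuals
  expect_equal(recon, x, ignore_attr = TRUE, tolerance = 1e-10)
  ref <- oracle_medpolish(x, max_iter = 10, tol = 1e-6)
  expect_equal(fit$residuals, ref$residuals, ignore_attr = TRUE,
               tolerance = 1e-8)

  shifted <- median_polish(x + 7, max_iter = 10, tol = 1e-6)
  expect_equal(shifted$overall, fit$overall + 7, tolerance = 1e-8)
  expect_equal(shifted$residuals, fit$residuals, tolerance = 1e-8)
})

test_that("PCA variance fractions match an independent eigendecomposition", {
  set.seed(56)
  vals <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  pca <- pca_decompose(vals)
  ev <- eigen(cov(t(vals)), symmetric = TRUE)$values
  expect_equal(pca$variance_explained,
               (ev / sum(ev))[seq_along(pca$variance_explained)],
               tolerance = 1e-10)
  # full reconstruction
  centered <- t(vals) - matrix(colMeans(t(vals)), 10, 30, byrow = TRUE)
  recon <- pca$scores %*% t(pca$coefficients)
  expect_equal(recon, centered, ignore_attr = TRUE, tolerance = 1e-8)
  # rank-1 input concentrates all variance on the first component
  r1 <- outer(rnorm(20), rnorm(8))
  dimnames(r1) <- list(sprintf("g%d", 1:20), sprintf("s%d", 1:8))
  expect_equal(pca_decompose(r1)$variance_explained[1], 1, tolerance = 1e-9)
})

test_that("PCA sign convention makes the top coefficient positive", {
  set.seed(57)
  vals <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  pca <- pca_decompose(vals)
  tops <- apply(pca$coefficients, 2, function(co) co[which.max(abs(co))])
  expect_true(all(tops > 0))
  # flipping the data sign leaves variance fractions unchanged
  pca2 <- pca_decompose(-vals)
  expect_equal(pca2$variance_explained, pca$variance_explained,
               tolerance = 1e-10)
})

test_that("contributing_genes applies a strict absolute threshold", {
  pca <- structure(list(
    scores = matrix(0, 2, 1),
    coefficients = matrix(c(0.06, -0.07, 0.01), 3, 1,
                          dimnames = list(c("g1", "g2", "g3"), NULL)),
    variance_explained = 1), class = "pca_result")
  out <- contributing_genes(pca, 1, threshold = 0.05)
  expect_identical(out$gene_id, c("g2", "g1"))
  expect_identical(nrow(contributing_genes(pca, 1, threshold = 1.1)), 0L)

  set.seed(58)
  co <- rnorm(100, 0, 0.05)
  pca$coefficients <- matrix(co, 100, 1,
                             dimnames = list(sprintf("g%d", 1:100), NULL))
  expect_identical(nrow(contributing_genes(pca, 1, 0.05)),
                   sum(abs(co) > 0.05))
})

test_that("first_sex_separating_pc finds the planted sex axis", {
  set.seed(59)
  n_pairs <- 10; n_s <- 2 * n_pairs; n_g <- 200
  md <- toy_pair_metadata(n_pairs)
  # three dominant non-sex factors, then a weaker consistent sex axis
  factor_scores <- matrix(rnorm(n_s * 3), n_s) %*% diag(c(12, 9, 6))
  loadings <- qr.Q(qr(matrix(rnorm(n_g * 4), n_g)))
  sex_scores <- ifelse(md$sex == "F", 2, -2)
  vals <- loadings[, 1:3] %*% t(factor_scores) +
    loadings[, 4, drop = FALSE] %*% t(sex_scores) +
    matrix(rnorm(n_g * n_s, 0, 0.05), n_g)
  dimnames(vals) <- list(sprintf("g%03d", 1:n_g), md$sample_id)
  pca <- pca_decompose(vals)
  res <- first_sex_separating_pc(pca, md, "pair")
  expect_identical(res$component, 4L)

  # sex as the only structure puts the separation on the first component
  vals1 <- loadings[, 4, drop = FALSE] %*% t(sex_scores) +
    matrix(rnorm(n_g * n_s, 0, 0.05), n_g)
  dimnames(vals1) <- dimnames(vals)
  expect_identical(first_sex_separating_pc(pca_decompose(vals1), md,
                                           "pair")$component, 1L)

  # swapping the labels keeps the index and negates the t statistic
  md_swap <- md
  md_swap$sex <- ifelse(md$sex == "F", "M", "F")
  res_swap <- first_sex_separating_pc(pca, md_swap, "pair")
  expect_identical(res_swap$component, res$component)
  expect_equal(res_swap$table$t[4], -res$table$t[4], tolerance = 1e-10)
})
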