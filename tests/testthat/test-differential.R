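test_that("build_pairing matches samples within strata", {
  # 1 F + 1 M in a stratum -> the unique pair
  d1 <- toy_design(1)
  expect_identical(nrow(d1$pairs), 1L)
  expect_identical(d1$pairs$female, "F1")
  expect_identical(d1$pairs$male, "M1")

  # 3 F + 3 M in one stratum: a perfect matching, reproducible under the seed
  md <- tibble::tibble(sample_id = c(paste0("f", 1:3), paste0("m", 1:3)),
                       sex = rep(c("F", "M"), each = 3), stratum = "s")
  d3a <- build_pairing(md, "stratum", seed = 7)
  d3b <- build_pairing(md, "stratum", seed = 7)
  expect_identical(d3a$pairs, d3b$pairs)
  expect_identical(nrow(d3a$pairs), 3L)
  expect_setequal(d3a$pairs$female, paste0("f", 1:3))
  expect_setequal(d3a$pairs$male, paste0("m", 1:3))

  # 3 F + 2 M -> 2 pairs + 1 unpaired
  md32 <- md[-6, ]
  d32 <- build_pairing(md32, "stratum", seed = 1)
  expect_identical(nrow(d32$pairs), 2L)
  expect_identical(nrow(d32$unpaired), 1L)
  expect_true(startsWith(d32$unpaired$sample_id, "f"))

  # a stratum lacking one sex reports all its samples unpaired
  md_single <- tibble::tibble(sample_id = c("a", "b"), sex = c("F", "F"),
                              stratum = "s")
  ds <- build_pairing(md_single, "stratum")
  expect_identical(nrow(ds$pairs), 0L)
  expect_identical(nrow(ds$unpaired), 2L)
})

test_that("paired t-test matches the textbook value on differences [1,2,3]", {
  x <- toy_paired_expr(f = c(1, 2, 3), m = c(0, 0, 0))
  de <- paired_ttest(x, toy_design(3))
  expect_equal(de$table$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(de$table$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(de$table$p, 0.0742, tolerance = 1e-3)
  expect_equal(de$table$log2fc, 2)
})

test_that("paired t-test flags degenerate genes instead of producing NaN", {
  x <- toy_paired_expr(f = c(2, 2, 2), m = c(2, 2, 2))
  de <- paired_ttest(x, toy_design(3))
  expect_true(de$table$degenerate)
  expect_equal(de$table$p, 1)
  expect_equal(de$table$log2fc, 0)
  expect_false(anyNA(de$table$p_fdr))
})

test_that("swapping female/male labels negates t and log2fc, p unchanged", {
  set.seed(61)
  x <- toy_paired_expr(f = matrix(rnorm(20 * 5, 6), 20),
                       m = matrix(rnorm(20 * 5, 6), 20))
  md <- toy_pair_metadata(5)
  de <- paired_ttest(x, build_pairing(md, "pair"))
  md_swap <- md
  md_swap$sex <- ifelse(md$sex == "F", "M", "F")
  de_swap <- paired_ttest(x, build_pairing(md_swap, "pair"))
  expect_equal(de_swap$table$t, -de$table$t, tolerance = 1e-12)
  expect_equal(de_swap$table$log2fc, -de$table$log2fc, tolerance = 1e-12)
  expect_equal(de_swap$table$p, de$table$p, tolerance = 1e-12)
})

test_that("a design of self-pairs yields p = 1 for every gene", {
  set.seed(62)
  vals <- matrix(rnorm(10 * 4, 6), 10, 4,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  x <- expr_matrix(vals, scale = "log2")
  self <- structure(list(
    pairs = tibble::tibble(female = colnames(vals), male = colnames(vals),
                           stratum = colnames(vals)),
    blocking_keys = "self", seed = 1L,
    unpaired = tibble::tibble(sample_id = character(), stratum = character())),
    class = "paired_design")
  de <- paired_ttest(x, self)
  expect_true(all(de$table$p == 1))
})

test_that("paired and unpaired t-tests match stats::t.test", {
  set.seed(63)
  n_pairs <- 6
  f <- matrix(rnorm(50 * n_pairs, 6), 50)
  m <- matrix(rnorm(50 * n_pairs, 6), 50)
  de <- paired_ttest(toy_paired_expr(f, m), toy_design(n_pairs))
  for (i in c(1, 17, 50)) {
    tt <- t.test(f[i, ], m[i, ], paired = TRUE)
    expect_equal(de$table$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$table$p[i], tt$p.value, tolerance = 1e-10)
  }

  vals <- cbind(f, m)
  colnames(vals) <- c(sprintf("a%d", 1:n_pairs), sprintf("b%d", 1:n_pairs))
  rownames(vals) <- sprintf("g%d", 1:50)
  x <- expr_matrix(vals, scale = "log2")
  welch <- unpaired_ttest(x, sprintf("a%d", 1:n_pairs), sprintf("b%d", 1:n_pairs))
  pooled <- unpaired_ttest(x, sprintf("a%d", 1:n_pairs), sprintf("b%d", 1:n_pairs),
                           equal_var = TRUE)
  for (i in c(2, 25, 44)) {
    tw <- t.test(f[i, ], m[i, ])
    tp <- t.test(f[i, ], m[i, ], var.equal = TRUE)
    expect_equal(welch$table$p[i], tw$p.value, tolerance = 1e-10)
    expect_equal(welch$table$df[i], unname(tw$parameter), tolerance = 1e-10)
    expect_equal(pooled$table$p[i], tp$p.value, tolerance = 1e-10)
  }
})

test_that("unpaired t-test degenerate cases are flagged", {
  vals <- rbind(sep = c(0, 0, 1, 1), same = c(2, 2, 2, 2))
  colnames(vals) <- c("a1", "a2", "b1", "b2")
  x <- expr_matrix(vals, scale = "log2")
  de <- unpaired_ttest(x, c("a1", "a2"), c("b1", "b2"))
  expect_true(all(de$table$degenerate))
  expect_equal(de$table$p[1], .Machine$double.xmin)
  expect_true(is.infinite(de$table$t[1]))
  expect_equal(de$table$p[2], 1)
  expect_equal(de$table$t[2], 0)
})

test_that("BH adjustment matches the hand example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(64)
  for (k in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-15)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("SDEG calling applies both criteria strictly", {
  tbl <- tibble::tibble(
    gene_id = c("called_f", "weak_p", "boundary_fc", "called_m"),
    log2fc = c(0.70, 2.0, -log2(1.5), -0.9),
    p_fdr = c(0.15, 0.25, 0.01, 0.1))
  sd <- call_sdegs(fake_de_result(tbl), alpha = 0.2, fc_fold = 1.5)
  expect_identical(sd$female, "called_f")
  expect_identical(sd$male, "called_m")
  expect_false("weak_p" %in% sd$table$gene_id)      # pFDR not < 0.2
  expect_false("boundary_fc" %in% sd$table$gene_id) # strict > on |log2fc|
})

test_that("single-tissue ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(65)
  vals <- matrix(rnorm(30 * 8, 6), 30, 8,
                 dimnames = list(sprintf("g%d", 1:30),
                                 c(paste0("f", 1:4), paste0("m", 1:4))))
  x <- expr_matrix(vals, scale = "log2")
  md <- tibble::tibble(sample_id = colnames(vals),
                       sex = rep(c("F", "M"), each = 4), tissue = "PC")
  an <- two_way_anova(x, md)
  tt <- unpaired_ttest(x, paste0("f", 1:4), paste0("m", 1:4), equal_var = TRUE)
  expect_equal(an$table$p_sex, tt$table$p, tolerance = 1e-8)
  expect_true(all(is.na(an$table$p_interaction)))
})

test_that("two-way ANOVA matches car::Anova (types III and II)", {
  set.seed(66)
  # unbalanced design: 2-4 samples per (sex, tissue) cell
  md <- tibble::tibble(
    sex = c(rep("F", 3), rep("M", 2), rep("F", 4), rep("M", 3),
            rep("F", 2), rep("M", 4)),
    tissue = c(rep("PC", 5), rep("Sp", 7), rep("CNS", 6)))
  md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
  vals <- matrix(rnorm(5 * nrow(md), 6), 5,
                 dimnames = list(sprintf("g%d", 1:5), md$sample_id))
  x <- expr_matrix(vals, scale = "log2")

  for (tp in c(3, 2)) {
    an <- two_way_anova(x, md, type = tp)
    opts <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(opts), add = TRUE)
    for (i in 1:5) {
      df <- data.frame(y = vals[i, ], sex = factor(md$sex, c("F", "M")),
                       tissue = factor(md$tissue))
      a <- car::Anova(lm(y ~ sex * tissue, df), type = tp)
      expect_equal(an$table$p_sex[i], a["sex", "Pr(>F)"], tolerance = 1e-8)
      expect_equal(an$table$p_tissue[i], a["tissue", "Pr(>F)"], tolerance = 1e-8)
      expect_equal(an$table$p_interaction[i], a["sex:tissue", "Pr(>F)"],
                   tolerance = 1e-8)
    }
  }
})

test_that("ANOVA separates a pure sex effect from interaction", {
  hits_sex <- 0; quiet_int <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    md <- tibble::tibble(sex = rep(rep(c("F", "M"), each = 3), 3),
                         tissue = rep(c("PC", "Sp", "CNS"), each = 6))
    md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
    y <- rnorm(18, 6, 0.1) + ifelse(md$sex == "F", 1, -1)  # pure sex effect 2.0
    vals <- matrix(y, 1, dimnames = list("g1", md$sample_id))
    an <- two_way_anova(expr_matrix(vals, scale = "log2"), md)
    if (an$table$p_sex < 1e-6) hits_sex <- hits_sex + 1
    if (an$table$p_interaction > 0.05) quiet_int <- quiet_int + 1
  }
  expect_gte(hits_sex, 95)
  expect_gte(quiet_int, 95)
})

test_that("pure tissue effect leaves the sex p-value uniform", {
  set.seed(67)
  md <- tibble::tibble(sex = rep(rep(c("F", "M"), each = 3), 3),
                       tissue = rep(c("PC", "Sp", "CNS"), each = 6))
  md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
  tis_eff <- c(PC = 0, Sp = 2, CNS = -1)
  vals <- matrix(rnorm(200 * 18, 6, 0.3), 200,
                 dimnames = list(sprintf("g%03d", 1:200), md$sample_id))
  vals <- vals + matrix(tis_eff[md$tissue], 200, 18, byrow = TRUE)
  an <- two_way_anova(expr_matrix(vals, scale = "log2"), md)
  expect_gt(ks.test(an$table$p_sex, "punif")$p.value, 0.01)
})

test_that("a tissue-restricted sex effect is detected as interaction", {
  set.seed(68)
  md <- tibble::tibble(sex = rep(rep(c("F", "M"), each = 4), 3),
                       tissue = rep(c("PC", "Sp", "CNS"), each = 8))
  md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
  y <- rnorm(24, 6, 0.2) +
    ifelse(md$tissue == "PC" & md$sex == "F", 1.5, 0)
  vals <- matrix(y, 1, dimnames = list("g1", md$sample_id))
  an <- two_way_anova(expr_matrix(vals, scale = "log2"), md)
  expect_lt(an$table$p_interaction, 0.001)
  fcs <- abs(unlist(an$table[paste0("fc_", an$tissues)]))
  expect_identical(names(which.max(fcs)), "fc_PC")
})

test_that("an empty (sex, tissue) cell is an error naming the cell", {
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                       sex = c("F", "M", "F", "M", "F", "F"),
                       tissue = c("PC", "PC", "Sp", "Sp", "CNS", "CNS"))
  vals <- matrix(rnorm(12, 6), 2, dimnames = list(c("g1", "g2"), md$sample_id))
  expect_error(two_way_anova(expr_matrix(vals, scale = "log2"), md),
               "\\(M, CNS\\)")
})

test_that("call_tissue_genes applies the published criteria", {
  # anova table with two genes: one fails the all-tissue FC rule, one is a
  # clean Sp interaction gene
  tbl <- tibble::tibble(
    gene_id = c("gA", "gB"),
    p_sex = c(0.001, 0.5), p_tissue = c(0.5, 0.5),
    p_interaction = c(0.9, 0.01),
    p_fdr_sex = c(0.01, 0.6), p_fdr_tissue = c(0.6, 0.6),
    p_fdr_interaction = c(0.9, 0.10),
    fc_PC = c(log2(1.6), 0.1), fc_Sp = c(log2(1.6), 1.0),
    fc_CNS = c(log2(1.2), 0.05))
  an <- structure(list(table = tbl, tissues = c("PC", "Sp", "CNS"), type = 3,
                       tissue_col = "tissue"), class = "anova_result")
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:12),
                       sex = rep(rep(c("F", "M"), each = 2), 3),
                       tissue = rep(c("PC", "Sp", "CNS"), each = 4))
  vals <- matrix(7, 2, 12, dimnames = list(c("gA", "gB"), md$sample_id))
  x <- expr_matrix(vals, scale = "log2")
  calls <- call_tissue_genes(an, x, md, alpha = 0.2, fc_fold = 1.5)
  # gA passes pFDR_sex but FC 1.2 in CNS fails the in-all-tissues rule
  expect_false("gA" %in% calls$sex_effect$gene_id)
  # gB: interaction pFDR 0.10, FC 2.0 only in Sp, expressed everywhere
  expect_identical(calls$interaction$Sp$gene_id, "gB")
  expect_identical(calls$interaction$Sp$direction, "female")
  expect_identical(nrow(calls$interaction$PC), 0L)
})

test_that("call_tissue_genes equals a brute-force re-application", {
  set.seed(69)
  n <- 200
  tissues <- c("PC", "Sp")
  tbl <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    p_sex = runif(n), p_tissue = runif(n), p_interaction = runif(n),
    fc_PC = rnorm(n, 0, 0.8), fc_Sp = rnorm(n, 0, 0.8))
  tbl$p_fdr_sex <- bh_adjust(tbl$p_sex)
  tbl$p_fdr_tissue <- bh_adjust(tbl$p_tissue)
  tbl$p_fdr_interaction <- bh_adjust(tbl$p_interaction)
  an <- structure(list(table = tbl, tissues = tissues, type = 3,
                       tissue_col = "tissue"), class = "anova_result")
  md <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                       sex = rep(rep(c("F", "M"), each = 2), 2),
                       tissue = rep(tissues, each = 4))
  vals <- matrix(runif(n * 8, 0, 12), n,
                 dimnames = list(tbl$gene_id, md$sample_id))
  x <- expr_matrix(vals, scale = "log2")
  calls <- call_tissue_genes(an, x, md, alpha = 0.2, fc_fold = 1.5,
                             expr_threshold = 6)

  cut <- log2(1.5)
  fc <- cbind(tbl$fc_PC, tbl$fc_Sp)
  sex_expected <- tbl$gene_id[
    tbl$p_fdr_sex < 0.2 &
      abs(fc[, 1]) > cut & abs(fc[, 2]) > cut &
      sign(fc[, 1]) == sign(fc[, 2])]
  expect_identical(calls$sex_effect$gene_id, sex_expected)

  for (k in 1:2) {
    tis <- tissues[k]
    ids_f <- md$sample_id[md$tissue == tis & md$sex == "F"]
    ids_m <- md$sample_id[md$tissue == tis & md$sex == "M"]
    gate <- rowSums(vals[, ids_f] > 6) == 2 | rowSums(vals[, ids_m] > 6) == 2
    expected <- tbl$gene_id[tbl$p_fdr_interaction < 0.2 &
                              abs(fc[, k]) > cut & gate]
    expect_identical(calls$interaction[[tis]]$gene_id, expected)
  }
})

test_that("on null data the SDEG count is null-consistent under permutation", {
  set.seed(70)
  n_pairs <- 5
  f <- matrix(rnorm(300 * n_pairs, 6, 0.3), 300)
  m <- matrix(rnorm(300 * n_pairs, 6, 0.3), 300)
  x <- toy_paired_expr(f, m)
  design <- toy_design(n_pairs)
  d <- f - m
  sdeg_count <- function(data, signs) {
    ds <- sweep(data, 2, signs, "*")
    mu <- rowMeans(ds)
    s <- sqrt(rowSums((ds - mu)^2) / (ncol(ds) - 1))
    p <- 2 * pt(-abs(mu / (s / sqrt(ncol(ds)))), df = ncol(ds) - 1)
    sum(bh_adjust(p) < 0.2 & abs(mu) > log2(1.5))
  }
  pt_res <- permutation_pvalue(sdeg_count, d, design, B = 200, seed = 3,
                               tail = "greater", exhaustive = FALSE)
  expect_gte(pt_res$p, 0.05)
})
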