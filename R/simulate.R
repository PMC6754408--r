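# Synthetic-data generators. They emulate the statistical structure of
# multi-dataset immune RNA-seq profiling -- dominant cell-type effects, batch
# (dataset) and age effects, small sex effects on sex-chromosome genes plus
# macrophage-restricted autosomal genes, an interferon-stimulated gene (ISG)
# module whose female-upward shift is amplified by IFN stimulation, and
# chromatin accessibility whose variance decreases with mean intensity --
# together with ground-truth tables, so every downstream test is checkable
# without external data.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) stop("a single numeric seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Defines the factorial design and effect hierarchy of a synthetic immune
#' expression study. Defaults mirror a two-dataset design over the 11 major
#' immunocyte lineages: per (sex, cell type, dataset) there are `n_replicates`
#' samples, cell-type effects dominate (SD 2.0 in log2 units), dataset (batch)
#' and age effects are intermediate, and residual noise is small.
#'
#' @param n_genes Number of genes.
#' @param cell_types Character vector of cell-type labels.
#' @param datasets Named list; each element is `list(n_replicates =, batch_sd =,
#'   age_groups =)`. Replicate r of a dataset is assigned its age groups
#'   cyclically, so pairing by dataset and age is well defined.
#' @param baseline_mean,baseline_sd Gene baseline expression distribution
#'   (log2 units).
#' @param celltype_sd SD of per-gene cell-type effects (log2); the dominant
#'   source of variation.
#' @param age_sd SD of per-gene age-group effects (log2).
#' @param sigma Residual SD (log2).
#' @param sex_effects Tibble with columns `gene` (index), `scope` (`"all"` or a
#'   cell-type label) and `effect` (log2 female - male). `NULL` for none.
#' @param isg_module `NULL`, or a list with `genes` (indices), `delta0`
#'   (baseline female-upward log2 shift), `induction_mean`, `induction_sd`
#'   (IFN induction distribution, log2), `delta_ifn` (extra induction in
#'   females, the sex x stimulation interaction) and optional `scope`
#'   (cell types carrying the baseline shift; default `"MF"`).
#' @param frac_x Fraction of genes labelled chromosome X (beyond genes forced
#'   to X/Y by their sex effects).
#' @param seed Mandatory integer seed; identical config gives bitwise-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 10000,
                       cell_types = c("GN", "DC", "MF", "B", "B1a", "T4",
                                      "T8", "Treg", "NK", "NKT", "Tgd"),
                       datasets = list(
                         A = list(n_replicates = 3, batch_sd = 0.5,
                                  age_groups = c("young", "adult", "old")),
                         B = list(n_replicates = 3, batch_sd = 0.5,
                                  age_groups = "6wk")),
                       baseline_mean = 6, baseline_sd = 2,
                       celltype_sd = 2, age_sd = 0.25, sigma = 0.3,
                       sex_effects = NULL, isg_module = NULL,
                       frac_x = 0.04, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma <= 0 || celltype_sd <= 0 || baseline_sd <= 0 || age_sd <= 0) {
    stop("all SDs must be > 0")
  }
  if (is.null(names(datasets))) stop("datasets must be a named list")
  for (d in datasets) {
    if (d$n_replicates < 1) stop("n_replicates must be >= 1 in every dataset")
  }
  if (!is.null(sex_effects)) {
    sex_effects <- as_tibble(sex_effects)
    stopifnot(all(c("gene", "scope", "effect") %in% names(sex_effects)))
    bad <- setdiff(setdiff(sex_effects$scope, "all"), cell_types)
    if (length(bad)) stop("sex-effect scope references unknown cell type(s): ",
                          paste(unique(bad), collapse = ", "))
    if (any(sex_effects$gene < 1 | sex_effects$gene > n_genes)) {
      stop("sex-effect gene index out of range")
    }
  }
  if (!is.null(isg_module)) {
    stopifnot(is.list(isg_module), !is.null(isg_module$genes))
    isg_module$delta0 <- isg_module$delta0 %||% 0.15
    isg_module$induction_mean <- isg_module$induction_mean %||% 3
    isg_module$induction_sd <- isg_module$induction_sd %||% 0.5
    isg_module$delta_ifn <- isg_module$delta_ifn %||% 0.30
    isg_module$scope <- isg_module$scope %||% "MF"
    if (any(isg_module$genes < 1 | isg_module$genes > n_genes)) {
      stop("ISG module gene index out of range")
    }
  }
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 datasets = datasets, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, celltype_sd = celltype_sd,
                 age_sd = age_sd, sigma = sigma, sex_effects = sex_effects,
                 isg_module = isg_module, frac_x = frac_x,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_metadata_grid <- function(config, stimulation = "none") {
  rows <- list()
  for (ds in names(config$datasets)) {
    d <- config$datasets[[ds]]
    ages <- d$age_groups
    for (ct in config$cell_types) {
      for (sex in c("F", "M")) {
        for (r in seq_len(d$n_replicates)) {
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sprintf("%s_%s_%s_%d", ds, ct, sex, r),
            sex = sex, cell_type = ct, dataset = ds,
            age_group = ages[((r - 1) %% length(ages)) + 1],
            tissue = NA_character_, stimulation = stimulation,
            replicate = r)
        }
      }
    }
  }
  bind_rows(rows)
}

sim_gene_chromosomes <- function(config) {
  chrom <- sample(as.character(1:19), config$n_genes, replace = TRUE)
  n_x <- round(config$frac_x * config$n_genes)
  if (n_x > 0) chrom[sample.int(config$n_genes, n_x)] <- "X"
  se <- config$sex_effects
  if (!is.null(se)) {
    pan <- se[se$scope == "all", ]
    chrom[pan$gene[pan$effect > 0]] <- "X"
    chrom[pan$gene[pan$effect < 0]] <- "Y"
  }
  chrom
}

sex_effect_matrix <- function(config) {
  # genes x cell_types matrix of the true log2 (F - M) effect
  eff <- matrix(0, config$n_genes, length(config$cell_types),
                dimnames = list(NULL, config$cell_types))
  se <- config$sex_effects
  if (!is.null(se)) {
    for (i in seq_len(nrow(se))) {
      if (se$scope[i] == "all") eff[se$gene[i], ] <- eff[se$gene[i], ] + se$effect[i]
      else eff[se$gene[i], se$scope[i]] <- eff[se$gene[i], se$scope[i]] + se$effect[i]
    }
  }
  isg <- config$isg_module
  if (!is.null(isg) && isg$delta0 != 0) {
    scope <- if (identical(isg$scope, "all")) config$cell_types else isg$scope
    eff[isg$genes, scope] <- eff[isg$genes, scope] + isg$delta0
  }
  eff
}

#' Simulate an immune expression study
#'
#' Draws log2 expression as gene baseline + cell-type effect + dataset batch
#' effect + age effect + half the true sex effect (signed by sex) + Gaussian
#' noise, floored at 0 (mirroring a floor-at-1-FPKM rule before log2).
#'
#' @param config A [sim_config()].
#' @return A list with `expr` ([expr_matrix()], log2 scale), `metadata`
#'   (tibble), `truth` (tibble: gene_id, chromosome, isg, module, scope,
#'   effect) and `components` (internal random effects, reused by
#'   [simulate_ifn_response()]).
#' @export
simulate_immune_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    meta <- sim_metadata_grid(config)
    n_g <- config$n_genes
    chrom <- sim_gene_chromosomes(config)
    baseline <- rnorm(n_g, config$baseline_mean, config$baseline_sd)
    ct_eff <- matrix(rnorm(n_g * length(config$cell_types), 0, config$celltype_sd),
                     n_g, dimnames = list(NULL, config$cell_types))
    batch <- vapply(names(config$datasets), function(ds) {
      rnorm(n_g, 0, config$datasets[[ds]]$batch_sd)
    }, numeric(n_g))
    all_ages <- unique(unlist(lapply(config$datasets, `[[`, "age_groups")))
    age_eff <- matrix(rnorm(n_g * length(all_ages), 0, config$age_sd),
                      n_g, dimnames = list(NULL, all_ages))
    sex_eff <- sex_effect_matrix(config)

    vals <- matrix(0, n_g, nrow(meta))
    for (j in seq_len(nrow(meta))) {
      s <- meta[j, ]
      mu <- baseline + ct_eff[, s$cell_type] + batch[, s$dataset] +
        age_eff[, s$age_group] +
        (if (s$sex == "F") 0.5 else -0.5) * sex_eff[, s$cell_type]
      vals[, j] <- mu + rnorm(n_g, 0, config$sigma)
    }
    vals <- pmax(vals, 0)
    gene_ids <- sprintf("g%05d", seq_len(n_g))
    colnames(vals) <- meta$sample_id
    rownames(vals) <- gene_ids

    isg <- config$isg_module
    is_isg <- rep(FALSE, n_g)
    module <- rep(NA_character_, n_g)
    if (!is.null(isg)) {
      is_isg[isg$genes] <- TRUE
      module[isg$genes] <- paste0("C", ((seq_along(isg$genes) - 1) %% 5) + 1)
    }
    scope <- rep(NA_character_, n_g)
    effect <- numeric(n_g)
    se <- config$sex_effects
    if (!is.null(se)) {
      scope[se$gene] <- se$scope
      effect[se$gene] <- se$effect
    }
    truth <- tibble(gene_id = gene_ids, chromosome = chrom, isg = is_isg,
                    module = module, scope = scope, effect = effect)
    expr <- expr_matrix(vals, gene_ids = gene_ids,
                        gene_chromosome = chrom, scale = "log2")
    list(expr = expr, metadata = meta, truth = truth,
         components = list(baseline = baseline, ct_eff = ct_eff,
                           batch = batch, age_eff = age_eff,
                           sex_eff = sex_eff))
  })
}

#' Append IFN-stimulated samples to a simulated study
#'
#' Adds stimulated samples (triplicates per sex, dose `IFN_10k`, for the
#' stimulated cell types; plus an `IFN_1k` arm for B cells when present) in
#' which ISG-module genes gain a gene-specific induction plus, in females, the
#' sex-by-stimulation interaction `delta_ifn`. Non-ISG genes are unchanged in
#' expectation.
#'
#' @param config The [sim_config()] used for `base`; must carry `isg_module`.
#' @param base Result of [simulate_immune_expression()].
#' @param stim_cell_types Cell types receiving stimulation.
#' @param stim_dataset Dataset label hosting the stimulation arm.
#' @return A list like `base` with stimulated samples appended and `truth`
#'   gaining `induction` and `delta_ifn` columns.
#' @export
simulate_ifn_response <- function(config, base,
                                  stim_cell_types = intersect(c("B", "GN", "MF"),
                                                              config$cell_types),
                                  stim_dataset = "B") {
  stopifnot(inherits(config, "sim_config"))
  isg <- config$isg_module
  if (is.null(isg)) stop("config has no isg_module")
  if (is.null(base$components)) stop("base must come from simulate_immune_expression()")
  if (!stim_dataset %in% names(config$datasets)) stop("unknown stim_dataset")
  with_seed(config$seed + 1L, {
    n_g <- config$n_genes
    induction <- numeric(n_g)
    induction[isg$genes] <- pmax(rnorm(length(isg$genes), isg$induction_mean,
                                       isg$induction_sd), 0)
    arms <- tibble(cell_type = stim_cell_types, stimulation = "IFN_10k")
    if ("B" %in% stim_cell_types) {
      arms <- bind_rows(arms, tibble(cell_type = "B", stimulation = "IFN_1k"))
    }
    d <- config$datasets[[stim_dataset]]
    comp <- base$components
    rows <- list()
    cols <- list()
    for (k in seq_len(nrow(arms))) {
      ct <- arms$cell_type[k]
      stim <- arms$stimulation[k]
      dose_scale <- if (stim == "IFN_1k") 0.5 else 1
      for (sex in c("F", "M")) {
        for (r in 1:3) {
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sprintf("%s_%s_%s_%s_%d", stim_dataset, ct, sex, stim, r),
            sex = sex, cell_type = ct, dataset = stim_dataset,
            age_group = d$age_groups[1], tissue = NA_character_,
            stimulation = stim, replicate = r)
          mu <- comp$baseline + comp$ct_eff[, ct] + comp$batch[, stim_dataset] +
            comp$age_eff[, d$age_groups[1]] +
            (if (sex == "F") 0.5 else -0.5) * comp$sex_eff[, ct] +
            dose_scale * (induction + (if (sex == "F") 1 else 0) *
                            ifelse(induction > 0, isg$delta_ifn, 0))
          cols[[length(cols) + 1]] <- pmax(mu + rnorm(n_g, 0, config$sigma), 0)
        }
      }
    }
    new_meta <- bind_rows(rows)
    new_vals <- do.call(cbind, cols)
    colnames(new_vals) <- new_meta$sample_id
    vals <- cbind(base$expr$values, new_vals)
    meta <- bind_rows(base$metadata, new_meta)
    truth <- base$truth
    truth$induction <- induction
    truth$delta_ifn <- ifelse(induction > 0, isg$delta_ifn, 0)
    expr <- expr_matrix(vals, gene_ids = base$truth$gene_id,
                        gene_chromosome = base$truth$chromosome, scale = "log2")
    list(expr = expr, metadata = meta, truth = truth, components = comp)
  })
}

#' Default intensity-dependent accessibility noise
#'
#' SD halves per +2 log2 units of mean intensity, anchored at `sd_ref` for the
#' lowest intensity `m0`.
#'
#' @param sd_ref SD at intensity `m0`.
#' @param m0 Anchor intensity (log2).
#' @return A function mapping mean log2 intensity to SD.
#' @export
halving_sd <- function(sd_ref = 0.5, m0 = 2) {
  function(m) sd_ref * 2^(-(m - m0) / 2)
}

#' Simulate OCR accessibility with intensity-dependent variance
#'
#' Per OCR, a mean log2 intensity is drawn uniformly from `intensity_range`;
#' female and male replicate values are normal around `mean +/- effect/2` with
#' SD `variance_fn(mean)`.
#'
#' @param n_ocrs Number of OCRs.
#' @param intensity_range Range of mean log2 intensities.
#' @param variance_fn Function mapping mean intensity to SD (monotone
#'   non-increasing by default; see [halving_sd()]).
#' @param planted_dos `NULL` or a tibble with columns `ocr` (index) and
#'   `effect` (log2 female - male).
#' @param n_replicates Replicates per sex.
#' @param class_probs Named probabilities for annotation classes.
#' @param ocrs_per_gene Consecutive OCRs sharing an associated gene.
#' @param seed Integer seed.
#' @return A list with `ocr` ([ocr_table()]), `metadata` (tibble) and `truth`
#'   (tibble: ocr_id, mean_intensity, effect).
#' @export
simulate_ocr_accessibility <- function(n_ocrs, intensity_range = c(2, 10),
                                       variance_fn = halving_sd(),
                                       planted_dos = NULL, n_replicates = 2,
                                       class_probs = c(TSS = 0.2, gene_body = 0.4,
                                                       distal_enhancer = 0.3,
                                                       other = 0.1),
                                       ocrs_per_gene = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(planted_dos)) {
    planted_dos <- as_tibble(planted_dos)
    if (any(planted_dos$ocr < 1 | planted_dos$ocr > n_ocrs)) {
      stop("planted effect on nonexistent OCR")
    }
  }
  with_seed(seed, {
    m <- runif(n_ocrs, intensity_range[1], intensity_range[2])
    sds <- variance_fn(m)
    if (any(sds <= 0)) stop("variance_fn must return positive SDs")
    effect <- numeric(n_ocrs)
    if (!is.null(planted_dos)) effect[planted_dos$ocr] <- planted_dos$effect
    f_vals <- matrix(rnorm(n_ocrs * n_replicates, m + effect / 2, sds),
                     n_ocrs, n_replicates)
    m_vals <- matrix(rnorm(n_ocrs * n_replicates, m - effect / 2, sds),
                     n_ocrs, n_replicates)
    vals <- cbind(f_vals, m_vals)
    samp <- c(sprintf("F_%d", seq_len(n_replicates)),
              sprintf("M_%d", seq_len(n_replicates)))
    colnames(vals) <- samp
    ocr_id <- sprintf("ocr%06d", seq_len(n_ocrs))
    ranges <- tibble(
      ocr_id = ocr_id, chrom = "chr1",
      start = seq_len(n_ocrs) * 1000L,
      end = seq_len(n_ocrs) * 1000L + 500L,
      annotation_class = sample(names(class_probs), n_ocrs, replace = TRUE,
                                prob = class_probs),
      associated_gene = sprintf("g%05d", (seq_len(n_ocrs) - 1) %/% ocrs_per_gene + 1)
    )
    metadata <- tibble(sample_id = samp,
                       sex = rep(c("F", "M"), each = n_replicates))
    list(ocr = ocr_table(vals, ranges), metadata = metadata,
         truth = tibble(ocr_id = ocr_id, mean_intensity = m, effect = effect))
  })
}

#' Simulate human/mouse ortholog comparison tables
#'
#' Builds a human differential-expression summary (log2 fold change and qFDR),
#' an ortholog map with a configurable unmapped fraction, a mouse fold-change
#' table in which a fraction `concordance` of the human sex-biased genes keep
#' their fold-change direction, and a small mouse expression matrix for
#' expression gating.
#'
#' @param n_genes Number of human genes.
#' @param n_human_de Number of human genes with qFDR < 0.05.
#' @param concordance Probability a human sex-biased gene keeps its direction
#'   in mouse.
#' @param unmapped_frac Fraction of human genes without a mouse ortholog.
#' @param n_mouse_samples Columns of the mouse expression matrix.
#' @param seed Integer seed.
#' @return A list with `human` (tibble: symbol, log2fc, qfdr), `map` (tibble:
#'   human_symbol, mouse_symbol), `mouse_fc` (tibble: symbol, log2fc) and
#'   `mouse_expr` ([expr_matrix()], linear scale).
#' @export
simulate_ortholog_tables <- function(n_genes = 2000, n_human_de = 300,
                                     concordance = 0.7, unmapped_frac = 0.05,
                                     n_mouse_samples = 6, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (concordance < 0 || concordance > 1) stop("concordance must be in [0, 1]")
  if (n_human_de > n_genes) stop("n_human_de cannot exceed n_genes")
  with_seed(seed, {
    hs <- sprintf("HS%05d", seq_len(n_genes))
    de_idx <- sample.int(n_genes, n_human_de)
    qfdr <- runif(n_genes, 0.05, 1)
    qfdr[de_idx] <- runif(n_human_de, 0, 0.0499)
    log2fc <- rnorm(n_genes, 0, 0.05)
    log2fc[de_idx] <- sample(c(-1, 1), n_human_de, replace = TRUE) *
      (abs(rnorm(n_human_de, 0, 0.15)) + 0.02)
    mapped <- runif(n_genes) >= unmapped_frac
    ms <- ifelse(mapped, sprintf("Ms%05d", seq_len(n_genes)), NA_character_)
    map <- tibble(human_symbol = hs[mapped], mouse_symbol = ms[mapped])
    keep_dir <- runif(n_genes) < concordance
    mouse_fc <- ifelse(keep_dir, sign(log2fc), -sign(log2fc)) *
      (abs(rnorm(n_genes, 0, 0.15)) + 0.02)
    mouse_tbl <- tibble(symbol = ms[mapped], log2fc = mouse_fc[mapped])
    expr <- matrix(abs(rnorm(sum(mapped) * n_mouse_samples, 5, 2)),
                   sum(mapped), n_mouse_samples,
                   dimnames = list(ms[mapped],
                                   sprintf("ms_s%d", seq_len(n_mouse_samples))))
    # a handful of unexpressed mouse genes exercise the expression gate
    off <- sample.int(sum(mapped), max(1, round(0.02 * sum(mapped))))
    expr[off, ] <- 0
    list(human = tibble(symbol = hs, log2fc = log2fc, qfdr = qfdr),
         map = map, mouse_fc = mouse_tbl,
         mouse_expr = expr_matrix(expr, scale = "linear"))
  })
}
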