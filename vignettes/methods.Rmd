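---
title: "Statistical methods in sexdimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in sexdimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdimorph)
library(dplyr)
```

# Overview

`sexdimorph` implements a pipeline for detecting sex differences in immune
transcriptomes and chromatin accessibility:

1. **Paired differential expression** between matched female/male profiles,
   with permutation-based significance as a cross-check.
2. **Pre-ranked gene-set enrichment** on the moderated ranking statistic.
3. **Signature shift tests** for small, coordinated fold-change shifts of a
   gene module (for example an interferon-stimulated gene signature).
4. **Sex-by-tissue interaction calling** via two-way ANOVA.
5. **Intensity-adjusted differential accessibility** via a windowed MAD
   z-test.
6. **Cross-species direction-consistency** of sex-biased genes through
   ortholog mapping.
7. A first-class **synthetic-data generator** whose ground truth drives the
   test suite.

Everything below is reproducible from the generator; no external data are
required.

# Paired differential expression

Profiles are paired within strata (cell type, dataset, age group) by
`build_pairing()`. For each gene, `paired_ttest()` computes the within-pair
female minus male log2 difference $d_i$ and the classical paired statistic

$$ t = \frac{\bar d}{s_d / \sqrt{n}}, \qquad \text{df} = n - 1. $$

Degenerate rows (all $d_i$ equal to a constant zero difference) are reported
as $t = 0$, $p = 1$ rather than an error, so that fully null fixtures pass
through the pipeline. P-values are adjusted by Benjamini–Hochberg
(`bh_adjust()`), and `call_sdegs()` applies the joint criterion
*adjusted p below `alpha`* **and** *fold change above `fc_fold`* with strict
inequalities on both sides; genes exactly at a boundary are not called.

```{r paired-example}
cfg <- sim_config(
  n_genes = 2000, cell_types = "MF",
  datasets = list(A = list(n_replicates = 6, batch_sd = 0.5,
                           age_groups = "adult")),
  sex_effects = tibble::tibble(gene = 1:5, scope = "MF", effect = 1.5),
  seed = 1)
sim <- simulate_immune_expression(cfg)
design <- build_pairing(sim$metadata, c("cell_type", "dataset", "age_group"))
de <- paired_ttest(sim$expr, design)
call_sdegs(de)$table
```

## Permutation nulls

`permutation_pvalue()` supports two designs: within-pair sign flips for the
paired statistic and group-size-preserving label shuffles for two-sample
statistics. Monte-Carlo p-values use the add-one convention
$p = (1 + r)/(B + 1)$, which can never return zero. When the design space is
small (at most $2^{14}$ assignments) the test enumerates it exhaustively and
reports the exact $p = r/\text{total}$, which includes the identity
assignment and is therefore strictly positive as well.

# Pre-ranked gene-set enrichment

`gsea_preranked()` walks the ranked list, incrementing by
$|s_i|^p / \sum_{\text{hits}} |s|^p$ at set members and decrementing by
$1/(N - N_{\text{hit}})$ elsewhere; the enrichment score is the maximum
absolute excursion. The null is built from `B` random gene sets of matching
size, NES divides by the mean absolute null ES of matching sign, and the
default FDR follows the positive/negative pooling scheme of the original
method (a plain BH alternative is available via `fdr = "BH"`).

# Signature shift tests

Small coordinated shifts that never pass a per-gene threshold are detected
at the module level. `shift_test_two_sample()` compares the fold changes of
the signature genes against all background genes with a Welch t-test;
`paired_fc_comparison()` compares stimulation-induced fold changes between
sexes pair by pair, so a sex-by-stimulation interaction of the module shows
up as a nonzero mean paired difference. Both reduce to $t = 0$, $p = 1$ on
degenerate (constant) input, and both have permutation counterparts through
`permutation_pvalue()`.

# Sex-by-tissue interactions

`two_way_anova()` fits a gene-wise two-way model with sum-to-zero contrasts
and Type III sums of squares (Type II by option), sharing the QR residual
projectors across genes so that ten thousand genes fit in seconds.
`call_tissue_genes()` then calls a gene tissue-restricted when the
interaction survives FDR control and the largest per-tissue fold change
clears the fold threshold, with an expression gate that discards genes not
expressed in the relevant tissue.

# Intensity-adjusted differential accessibility

Accessibility noise shrinks with mean intensity, roughly halving per two
log2 units. A global z-test is therefore miscalibrated: it over-calls noisy
low-intensity regions and under-calls quiet high-intensity ones.
`mad_adjusted_test()` instead estimates the null scale locally: for each
region it takes the window of regions within `window_width/2` of its pooled
mean intensity (excluding the region itself, so a large own effect cannot
inflate its own null), sets $\sigma = 1.4826 \times \text{MAD}$ of the
window's female minus male differences, and reports
$z = d/\sigma$ with a two-sided normal p-value. Windows smaller than
`min_window` are expanded symmetrically in intensity rank and flagged; a
window with zero MAD falls back to the global MAD and is flagged.

The leave-one-out window is a deliberate choice: with the focal region
included, a strongly differential region widens its own null scale and
penalises itself. Excluding it keeps the null estimate independent of the
effect under test while changing nothing for null regions.

```{r atac-example}
simo <- simulate_ocr_accessibility(
  2000, planted_dos = tibble::tibble(ocr = 1:5, effect = 2.5), seed = 2)
res <- mad_adjusted_test(simo$ocr, simo$metadata)
call_dos(res)$table
```

# Cross-species consistency

`immvar_gene_filter()` removes genes below the per-sample 10% intensity
quantile in at least two thirds of samples of *both* sexes (an AND rule, so
a sex-specific gene is kept). `map_orthologs()` carries significant human
genes through an ortholog table, recording every exclusion with a reason
(`not_significant`, `no_ortholog`, `ambiguous_ortholog`,
`mouse_unexpressed`, `no_mouse_fc`) rather than dropping rows silently.
`direction_consistency_test()` then asks whether genes biased toward one
sex in humans keep their direction in mouse more often than chance, using a
hypergeometric tail (or a one-sided binomial alternative) at a ladder of
fold-change thresholds.

# The synthetic-data generator

`simulate_immune_expression()` draws log2 expression as an additive model:
a gene baseline (mean 6, SD 2), a gene-by-cell-type term (SD 2), a dataset
batch term, an age term, half the planted sex effect with opposite signs in
the two sexes, and residual noise (SD 0.3 by default), floored at zero.
Planted effects carry a `scope` (a cell type, or `"all"` for pan-immune
X/Y-like genes, which are labelled to sex chromosomes in the truth table).
An optional interferon-stimulated module adds a baseline female bias
`delta0`, a stimulation induction (mean 3 log2 units), and an extra female
interaction `delta_ifn` under stimulation via `simulate_ifn_response()`.
Accessibility data come from `simulate_ocr_accessibility()` with an
intensity-dependent noise scale (`halving_sd()`), and ortholog tables with
a tunable direction concordance from `simulate_ortholog_tables()`.

All generators take a mandatory seed, restore the caller's RNG state, and
return a tidy ground-truth table, which is what the acceptance suite tests
recall, FDR, and calibration against.

## Parameter defaults and rationale

* `alpha = 0.2`, `fc_fold = 1.5` for SDEG calling: a deliberately permissive
  screen for small dimorphic effects; the strict variant (0.05, 2-fold)
  suits interferon-module follow-up.
* `alpha = 0.05`, `fc_fold = 2` for accessibility calling, where effect
  sizes are larger and replicate counts smaller.
* `window_width = 1.0`, `min_window = 50` for the MAD test: one log2 unit
  is narrow enough to track the noise gradient, and 50 regions keep the MAD
  stable (the MAD of 50 normal draws has roughly 11% relative error).
* GSEA `min_size = 15`, `max_size = 500`, `q_cut = 0.25`: the conventional
  operating point for pre-ranked enrichment.
* Planted-effect magnitudes in the acceptance suite are drawn uniformly
  from 0.8 to 3.0 in absolute log2 value, matching the spread between the
  calling threshold (1.5-fold) and the strongest observed autosomal
  dimorphisms (~8-fold).

# Limitations

* The paired t-test assumes approximately normal within-pair differences;
  with very few pairs the permutation p-value is the more defensible
  number, and the exhaustive mode makes it exact.
* The MAD window assumes the noise scale varies smoothly with intensity;
  sharp discontinuities would blur across a window boundary.
* The generator's noise is homoscedastic Gaussian on the log2 scale; it is
  a calibration instrument, not a model of count overdispersion, so
  count-level methods should not be benchmarked against it.
* Direction-consistency p-values condition on the mapped, expressed gene
  universe; selection effects upstream of mapping are not modelled.
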