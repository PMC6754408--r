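Package: sexdimorph
Title: Sex-Biased Expression and Chromatin Accessibility Analysis for Immune Cell Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for detecting transcriptional and
    chromatin-accessibility sexual dimorphism across immune cell types:
    paired and pan-immune differential expression with sign-flip and
    label-shuffle permutation nulls, pre-ranked gene-set enrichment on the
    t statistic, interferon-signature fold-change shift tests, sex-by-tissue
    interaction calling by two-way ANOVA, an intensity-windowed
    MAD-adjusted test for differential open chromatin, and human-mouse
    direction-consistency testing. Ships a synthetic-data generator that
    emulates the factorial structure of multi-dataset immune profiling
    (dominant cell-type effects, batch and age effects, small sex effects
    concentrated on sex-chromosome genes plus macrophage-specific autosomal
    genes, an interferon-stimulated gene module, and accessibility data
    with intensity-dependent variance) so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    DESeq2,
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
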