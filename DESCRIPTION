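Package: flaxfta
Title: Variant-Allele-Frequency Association Screen for Flax Plant Type
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate-gene panels for polymorphisms associated with
    the flax (Linum usitatissimum) plant type (fiber flax versus linseed).
    Per-variety variant-allele-frequency (VAF) profiles over gene regions are
    read from VCF, filtered by read support, censused per gene and family,
    correlated with the binary plant type (Spearman, Pearson, Kendall,
    Mann-Whitney, Benjamini-Hochberg FDR), and classified as flax
    type-associated (FTA).  Varieties are clustered from VAF profiles
    (Euclidean distance, Ward's minimum variance), and a companion expression
    module provides CPM/log2/mean-centring preprocessing with gene and tissue
    clustering for heatmaps.  A synthetic-cohort generator emulates the
    two-group, low-coverage study design so the whole pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    ape,
    edgeR,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
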