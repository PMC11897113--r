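Package: sweetqtl
Title: Meta-Genetic Analysis of Fruit Sweetness QTLs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the meta-genetic dissection of a quantitative fruit
    trait such as melon flesh sweetness (total soluble solids, degrees Brix).
    Implements half-diallel mode-of-inheritance statistics (additive and
    dominance effects, degree of dominance, general combining ability,
    ANOVA-based broad-sense heritability), bulk-segregant QTL-seq scanning
    (SNP-index, delta SNP-index, sliding-window smoothing and threshold-based
    region calling), marker-level QTL analytics on inbred-line populations
    (permutation-thresholded single-marker scans, allelic effects and percent
    variance explained, pairwise epistasis, favorable-allele stacking,
    expected-versus-observed additivity regression), and multi-study
    pan-QTLome integration by genomic binning. A simulation suite generates
    half-diallel, single-seed-descent inbred-line, pooled-sequencing and
    multi-study inputs with ground-truth bookkeeping for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
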