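Package: chromdiverge
Title: Cis/Trans Classification of Chromatin Accessibility Divergence
    from Hybrid ATAC-Seq Counts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies evolutionary divergence in chromatin accessibility
    between two species into inheritance modes (additive, dominant,
    over/underdominant) and regulatory modes (cis, trans, cis+trans,
    cis-x-trans, compensatory) from parental and F1-hybrid allele-specific
    ATAC-seq read counts, following the statistical framework developed for
    hybrid transcriptomes.  Includes a negative-binomial allele-specific
    count simulator with configurable cis/trans effects, CPM-based low-count
    filtering, median-of-ratios normalization, PCA, Wald-type differential
    accessibility tests, a parental-versus-allelic ratio-divergence test,
    evolutionary effect sizes, peak-gene association statistics
    (chi-squared with Pearson residuals, Fisher exact, Welch, KS,
    ANOVA/Scheffe), FRIP quality scores, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
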