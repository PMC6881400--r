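Package: cistrans
Title: Cis and Trans Regulatory Divergence from Allele-Specific Expression in
    Reciprocal F1 Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and statistical classification of cis and trans
    regulatory divergence between two accessions from parental and reciprocal
    F1-hybrid RNA-seq read counts, with allele-specific expression (ASE) in the
    hybrids isolating cis effects. Implements median-of-ratios count
    normalization, a negative-binomial Wald test with trended dispersion
    shrinkage, Welch t-tests of parental versus allelic log-ratios,
    seven-category regulatory classification (cis-only, trans-only, enhancing,
    compensating, compensatory, conserved, ambiguous), the bias-prone standard
    and bias-free cross-replicate cis-trans correlation estimators,
    reciprocal-hybrid consensus calling of regulatory-divergence (RD) genes,
    inheritance-mode classification (additive, dominant, transgressive), and an
    allopolyploid homoeolog layer (syntenic triplet extraction, homoeolog
    expression bias, domestication change of homoeolog ratio and total, and
    association with RD status). Includes a seeded negative-binomial simulator
    of parental and allelic counts with known regulatory truth for calibration
    and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
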