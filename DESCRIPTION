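Package: transpco
Title: Trans-eQTL Mapping of Gene Modules with a PC-Based Omnibus Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects trans-acting expression quantitative trait loci (trans-eQTLs)
    that affect gene co-expression modules. A SNP is tested against all genes in a
    module jointly by projecting univariate association Z scores onto the module's
    expression principal components and combining six PC-based statistics
    (PCMinP, PCFisher, PCLC, WI, Wald, VC) into an omnibus p-value via their joint
    null distribution. Includes expression preprocessing and module detection,
    an individual-level genome scan with same-chromosome exclusion and
    permutation-based empirical FDR, a summary-statistics mode that approximates
    the module correlation matrix from null SNPs with an SNP-to-gene ratio gate
    and cross-mappability exclusion, LD clumping, a power/type-I simulation
    framework with PC1 and MinP comparators, and a synthetic-data generator for
    fully reproducible fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mvtnorm,
    limma,
    fgsea,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
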