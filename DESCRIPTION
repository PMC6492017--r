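Package: loyscan
Title: Loss-of-Y Detection and Arm-Level Aneuploidy Analysis from Segmented
    Copy-Number Data
Version: 0.1.0
Authors@R:
    person("LoYscan", "Developers", email = "loyscan@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify mosaic loss of the Y chromosome (LoY) in male
    tumor cohorts from SEG-format segmented copy-number data. Computes
    purity-adjusted arm- and chromosome-level copy-number indices, a Y index
    over the male-specific region, and a total autosomal aneuploidy index;
    classifies samples as LOY / RETAINED / UNCERTAIN from the modes of a
    kernel density fit; provides an expression-ratio and principal-component
    LoY caller for array data, Y-gene dosage screening, fold-change and
    expression-floor differential-expression filtering, hypergeometric
    gene-set enrichment, and the accompanying survival and association
    statistics. Includes a seeded synthetic cohort generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    yaml
Config/testthat/edition: 3
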