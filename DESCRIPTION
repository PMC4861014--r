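Package: paramut
Title: Context-Separated DMR Calling and Multi-Omic Candidate Triage for a
    Plant Paramutation System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for locating a paramutated locus from
    whole-genome bisulfite, small RNA, and mRNA sequencing summaries.
    Implements strand-pooled, 200-bp, context-separated (CG/CHG/CHH) binning
    of per-cytosine methylation calls with a replicate-consistent dual
    chi-square rule for differentially methylated regions, region-level
    binomial regression tests of methylation differences, trimmed mean of
    M-values (TMM) normalization of small RNA locus counts followed by
    Poisson regression on a three-level genotype factor, correlation-based
    four-class categorization of differentially expressed genes with a
    positional candidate filter, and McrBC/qPCR methylation and expression
    quantification. A synthetic-data generator with planted ground truth
    drives parameter-recovery and calibration tests so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
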