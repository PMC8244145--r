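Package: xcistate
Title: Calling X-Chromosome Inactivation Status from Allelic Expression,
    DNA Methylation and Chromatin Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls the X-chromosome inactivation (XCI) status of genes --
    escape, subject to XCI, or variable escape -- per gene and per sample.
    Implements a binomial confidence-interval caller for allelic (Xi/Xa)
    expression, promoter CpG-island DNA-methylation callers at bulk,
    per-read and allele-resolved resolution, normalized chromatin-mark
    quantification with female-vs-male (Xi:Xa) fold changes and metagene
    profiles, a vote-consensus random-forest ensemble predictor over seven
    epigenetic marks, cross-method reconciliation of variable-escape
    categories, and genotype association with XCI status including
    attributable risk and sex-stratified methylation QTL models. A seeded
    synthetic-data generator with planted XCI structure makes the full
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ranger
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
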