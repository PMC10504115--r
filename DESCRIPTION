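Package: twindmc
Title: Discriminating Monozygotic Twins by Recurrent Differentially
    Methylated CpG Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for discriminating individuals within a
    monozygotic twin pair from blood DNA methylation array data.
    Computes within-pair delta-beta values from normalized beta-value
    matrices, calls per-pair differentially methylated CpG sites (DMCs)
    at a beta-difference threshold, selects recurrent DMCs across a
    cohort with a two-criterion variability/divergence filter, tests
    gene-structure and CpG-island category enrichment, replicates the
    selected set in an independent cohort, and ranks candidate forensic
    markers. Includes a synthetic paired-twin cohort generator with
    planted recurrent DMCs and known ground truth for validating the
    selector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
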