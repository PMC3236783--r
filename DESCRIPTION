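Package: cnvassay
Title: Copy-Number Calling by qPCR and Paralog Ratio Test, with Assay Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assigning integer gene copy numbers from quantitative
    PCR (delta-delta-Ct) and paralog ratio test (PRT) measurements, sharing a
    maximum-likelihood integer-assignment engine, together with a generative
    simulator of both assays. The simulator reproduces the two failure modes
    that dominate real copy-number genotyping: amplification-efficiency
    mismatch between target and reference assays interacting with input DNA
    amount, and template degradation interacting with amplicon length. Method
    agreement is quantified with concordance matrices, replicate
    reproducibility, Bland-Altman limits of agreement and chi-squared
    comparison of call distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
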