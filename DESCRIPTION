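Package: ddcnv
Title: Absolute Copy Number Quantification from Droplet Digital PCR with
    Extreme-Phenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Poisson-based absolute quantification of droplet digital PCR
    (ddPCR) experiments and downstream copy-number-variant (CNV) analysis
    for extreme-phenotype case-control designs. Estimates template
    concentration per droplet from positive-droplet fractions with 95%
    confidence intervals, merges replicate wells at the droplet level,
    normalises duplexed target counts against a two-copy reference assay
    into copies per diploid genome, calls integer copy number with a
    CI-containment rule and exclusion/repeat logic, and tests CNV carriage
    against extreme blood-pressure group membership by covariate-adjusted
    logistic regression and rank-based tests. Includes a droplet-level and
    cohort-level simulator so the whole pipeline is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
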