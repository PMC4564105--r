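Package: ampliclone
Title: Rare Mutant Clone Detection and Passage Enrichment from Deep
    Amplicon Read Counts
Version: 1.0.0
Authors@R:
    person("Amplicon", "Maintainers", email = "maintainers@ampliclone.example.org",
           role = c("aut", "cre"))
Description: Detects rare circulating mutant clones from ultra-deep
    amplicon sequencing read counts and quantifies their enrichment
    across cell-culture passages.  Implements a trimmed log-odds
    background-error model with a k-sigma detection threshold, depth QC
    and positivity calling, exact two-sided cohort association, a
    random-effects negative binomial passage-enrichment regression
    (beta-dispersion panel and normal-intercept flavours), replicate
    concordance (ICC), a synthetic count-table generator emulating the
    assay, and a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lme4,
    MASS,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
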