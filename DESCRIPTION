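Package: methcall
Title: Consensus Differential Methylation Calling for Beta-Value Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome-wide DNA methylation beta-value matrices from
    CpG methylation microarrays, built around a stringent three-criteria
    consensus caller for differential methylation (a reference/case threshold
    rule, a mean beta-difference rule, and an unpaired t test adjusted by
    Westfall-Young step-down maxT permutation and Benjamini-Hochberg false
    discovery rate), with intersection of calls across multiple reference
    tissues, gene-level aggregation and ranking, probe and sample quality
    control, hypergeometric annotation enrichment (chromosome, cytoband,
    promoter CpG class, Polycomb targets, arbitrary gene sets), a sequence
    based promoter CpG-content classifier, methylation-expression concordance
    via z-score transformed expression, principal component and hierarchical
    clustering views, and a fully seeded synthetic-data generator with a
    planted-truth registry for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
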