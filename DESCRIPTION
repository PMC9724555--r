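Package: ibdbench
Title: Benchmarking Framework for Identity-by-Descent Segment Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark identity-by-descent (IBD) segment detection
    software. Extracts ground-truth IBD segments from coalescent local-tree
    tracks by most-recent-common-ancestor contiguity, prepares array- and
    sequencing-density phased haplotype panels (site filtering, minor-allele
    -frequency guided marker downsampling, incremental genotyping-error
    injection), scores reported IBD calls against truth with six
    length-stratified metrics (accuracy, length accuracy, length discrepancy,
    recall, power, accumulative power), and summarises calls as per-site
    coverage profiles and relatedness-degree assignments from total pairwise
    IBD sharing. Includes seeded synthetic-data generators with independent
    metric oracles so every stage is testable without external simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
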