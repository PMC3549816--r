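Package: delclust
Title: Calling Overlapping Deletions from Stretched Paired-End Mappings by
    Agglomerative Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic deletions, including overlapping deletions on
    different haplotypes, from paired-end reads mapped to a reference.
    Stretched read-pair mappings are represented as triangles in the
    (deletion start, deletion end) plane carrying a Gaussian ridge over the
    implied deletion size, and are merged bottom-up by agglomerative
    clustering under a normalized volume-intersection similarity score with
    a data-driven stopping threshold. Includes BAM and plain-table input
    with the standard quality filters, per-region visualization of
    mappings and calls, a mapping-level simulator for overlapping-deletion
    scenarios with ground truth, and an evaluator computing single/pair
    detection rates and mapping mis-assignment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
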