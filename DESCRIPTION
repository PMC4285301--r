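Package: poolscan
Title: Genome Scans for Parallel Ecotype Divergence from Pooled Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting parallel adaptive divergence from replicated
    pooled-sequencing allele counts in the popoolation2 'sync' format.
    Implements coverage subsampling with replacement, minor-allele-count SNP
    calling, per-contig Nei-style FST between sample pairs, quantile-threshold
    outlier detection with replicate consistency, tests of cross-location
    outlier sharing against a hypergeometric chance null, and SNP-level
    correlation tests for shared molecular mechanisms, together with a
    synthetic pool-seq data generator emulating a three-location,
    two-ecotype, two-replicate transcriptome study design.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
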