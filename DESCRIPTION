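Package: tomtomlite
Title: Fast Motif Similarity Search with Exact Binned Null Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores query position matrices (frequency PWMs or attribution
    CWMs) against a target motif database over every ungapped alignment and
    both orientations, and converts the maximum similarity score into a
    P-value using exact null distributions of the maximum built by dynamic
    programming over integer-binned column scores. Implements the Tomtom
    statistic with null-distribution caching across query-target pairs,
    hashing of redundant target-database columns, and an optional
    approximate median at the score-centering bottleneck. Includes readers
    and writers for MEME minimal motif format and JASPAR-style PFM text,
    Benjamini-Hochberg q-values and E-values, seqlet annotation against a
    motif database, and deterministic synthetic-motif generators for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
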