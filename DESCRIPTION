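Package: pairclip
Title: Adapter Trimming for Paired-End Reads by Reverse-Complement Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes 3' adapter read-through contamination from paired-end
    sequencing reads without knowing the adapter sequence. The trimming site
    is located by a two-stage mismatch-tolerant scan: the 5' prefix of each
    mate is reverse complemented and slid along the other mate, candidate
    insert lengths found in both directions are intersected, and candidates
    are validated largest-first by reverse-complementarity of the inferred
    DNA portions and similarity of the inferred adapter portions. Also
    provides a ground-truthed paired-end read simulator with a
    quality-driven substitution error model, and evaluation metrics
    (sensitivity, specificity, accuracy, Matthews correlation coefficient,
    trimmed-length distributions, and a label-free approximate
    true-positive count) for benchmarking trimmers.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    stringi,
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
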