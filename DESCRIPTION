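Package: repliseqr
Title: Replication Timing Profiles and Domain Segmentation from Repli-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts aligned Repli-Seq reads from four flow-sorted S-phase
    fractions (early, early-mid, late-mid, late) into continuous replication
    timing profiles, segments each genome into early, late and indeterminate
    replication domains with a three-state hidden Markov model with bivariate
    Gaussian emissions (k-means initialisation, Baum-Welch training, Viterbi
    decoding, minimum-run merging), classifies domains across cell lines as
    static or dynamic, and annotates domains with point-feature densities and
    median signal enrichments. Includes a synthetic Repli-Seq generator with
    planted domain structure, aneuploidy and feature densities so the whole
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    readr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Config/testthat/edition: 3
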