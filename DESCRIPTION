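Package: nucleocall
Title: Nucleosome Detection from Strand-Specific MNase-Seq Read Starts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls nucleosome positions from mapped single-end short reads of
    MNase-digested mononucleosomes. Read 5' starts are counted per strand and
    every candidate position is scored with a three-region Poisson
    likelihood-ratio statistic that contrasts the forward support, binding and
    reverse support regions against a robust, locally estimated background
    rate. Scores are converted to p- and q-values under an empirical null
    fitted by a truncated half-normal maximum-likelihood procedure, and
    discrete predictions are extracted at a chosen false discovery rate. The
    package also ships a strand-specific read simulator with a
    stable/phased/fuzzy/nucleosome-free chromatin feature model and truth
    tables, plus downstream analyses: dinucleotide periodicity profiles around
    dyads, phasing profiles at annotated anchors, adjacent-prediction
    distances, detection metrics against simulated truth, a total-correlation
    repeatability score and Pareto-front parameter selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
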