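Package: pirnangm
Title: piRNA Detection with n-Gram Markov Models and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Piwi-interacting RNAs (piRNAs) from nucleotide sequence
    alone. Known piRNAs are partitioned into homologous families by an
    iterative seed-and-collect procedure driven by (n-1)th-order Markov chain
    (n-gram) models; raw sliding-window log-likelihood similarities are
    calibrated into length-adjusted Z-scores against Monte-Carlo shuffled
    null ensembles; the per-family Z-score features feed a C-classification
    support vector machine with RBF kernel that labels candidate sequences
    and reports confidence probabilities. Includes a 1,364-feature k-mer
    counting baseline classifier, a stratified cross-validation / ROC / AUC
    evaluation harness, a ground-truth synthetic sequence generator for
    testing, and a command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
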