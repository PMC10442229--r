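Package: xirt
Title: Replication Timing and Chromosome Conformation Analysis of the Inactive X
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for replication-timing (RT) and
    chromosome-conformation analysis of X-chromosome inactivation. Implements
    bulk BrdU-IP Repli-seq RT scoring with low-count filtering, quantile
    normalization and replicate averaging; RT-class calling for
    differentiation (EtoE/EtoL/LtoE/LtoL) and SmcHD1 dependence (SD/SI/CL/CE);
    single-cell Repli-seq binarization with a two-state Gaussian hidden Markov
    model, percentage-replication scores, T10-90% replication-kinetics fits
    and single-cell RT (scRT) derivation; virtual 4C extraction from binned
    contact matrices with windowed binomial z-score interaction calling in
    far-cis and trans under FDR control; and feature-density enrichment by RT
    class. A seeded synthetic-data generator produces genomes, replication
    programs, single-cell and bulk count data and layered contact matrices so
    that every stage of the pipeline can be exercised and validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    Matrix,
    stats,
    methods,
    utils,
    minpack.lm,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
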