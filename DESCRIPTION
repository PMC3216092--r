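Package: tfcycle
Title: Transcription Factor Activity Inference and Dynamical Modelling of
    the Yeast Metabolic Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers time-dependent transcription factor activities
    (alpha-coefficients) from time-series expression and genome-wide
    promoter-binding data by robust log-linear regression, iteratively
    selects significant factors, scores activity profiles for periodicity
    by lag-autocorrelation with a permutation null, fits single sinusoids
    to obtain phases and amplitudes over the yeast metabolic cycle, labels
    cycle phases from the dissolved-oxygen trace, clusters activity
    profiles on their absolute values, estimates linear time-translation
    (dynamical) matrices with and without a non-negativity constraint, and
    extracts a directed regulatory network from the significant matrix
    entries. Includes a fully specified synthetic-data generator with
    ground truth so that every stage is testable end to end.
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
    igraph,
    jsonlite,
    MASS,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
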