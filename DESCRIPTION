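Package: bdifam
Title: Birth-Death-cis-Innovation Models of Transcription Factor Motif Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Organizes transcription factors (TFs) into motif families by
    projecting a TF-to-position-weight-matrix (PWM) bipartite association
    network onto its TF nodes, and models the resulting family-size
    distribution with a one-parameter neutral Birth-Death-cis-Innovation
    (BDI) process whose stationary law is a truncated logarithmic series
    p_i proportional to theta^i/i. Provides closed-form maximum-likelihood
    estimation of the redundancy parameter theta via the Lambert W function,
    parametric-bootstrap Kolmogorov-Smirnov goodness-of-fit tests, a
    size-threshold/singleton trim scan that isolates the model-consistent
    core of a distribution, an exact event-level (Gillespie) simulator of
    the BDI process with family-per-element envelope summaries, per-DNA-
    binding-domain outlier calls, cross-species scaling of theta with
    repertoire size, readers and writers for CIS-BP-style annotation tables
    and PWM files, and a synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
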