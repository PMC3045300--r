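Package: pyroclean
Title: Flowgram Denoising and Chimera Removal for Pyrosequenced Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage removal of noise from 454-style pyrosequenced PCR
    amplicons. The first stage clusters flowgrams with an expectation-
    maximization (EM) mixture model built on empirical signal-intensity
    distributions, removing pyrosequencing errors; the second stage clusters
    the denoised sequences with an EM model built on a PCR
    substitution/indel error model and a homopolymer-aware Needleman-Wunsch
    alignment, removing PCR point errors. An abundance-aware chimera
    classifier scores each sequence against spliced reconstructions from
    more abundant candidate parents via a binomial chimera index and a
    logistic decision rule. Includes reference-based evaluation tools (per
    base error rates, chimera labelling, OTU construction accuracy) and a
    seeded synthetic-community generator so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
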