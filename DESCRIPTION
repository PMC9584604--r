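Package: fretkin
Title: Kinetic Analysis of Single-Molecule FRET Traces from Ribosomal
    aa-tRNA Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and kinetic analysis of single-molecule FRET
    (smFRET) intensity traces reporting on aminoacyl-tRNA selection by the
    ribosome. Provides a Gillespie simulator for labeled continuous-time
    Markov kinetic schemes with photophysically realistic trace rendering
    (camera frame integration, Gaussian FRET noise, single-step
    photobleaching), segmental k-means hidden-Markov idealization with a
    compiled Viterbi decoder, dwell-time extraction with censoring,
    count/occupancy transition-rate estimation with trace-level bootstrap
    errors, truncation at the first long high-FRET dwell,
    post-synchronized population histograms and transition density plots,
    Hill dose-response fitting of accommodated fractions, and censored
    maximum-likelihood estimation of very slow accommodation and washout
    rates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
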