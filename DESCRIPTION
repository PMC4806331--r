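Package: mosaicnv
Title: Detection of Organ-Private Mosaic Copy Number Variants from
    Dual-Platform SNP Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting somatic mosaic (organ-private)
    copy number variants from multi-organ SNP array data assayed on two
    platforms of differing marker density. Provides per-sample quality
    control (MAPD and a genotype-cluster separation score), joint
    log2-ratio/B-allele-frequency hidden Markov model segmentation with
    mosaic sub-states, probe-count and event-type filtering, 50% reciprocal
    cross-platform validation, germline removal by all-organ intersection,
    and T-cell receptor locus annotation. Includes a synthetic multi-organ
    cohort generator with germline, mosaic and polyclonal TCR-rearrangement
    deletion events, and an interphase FISH aneusomy scoring framework with
    single-probe and dual-probe rules, so every stage is verifiable against
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
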