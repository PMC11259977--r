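Package: wgdchronos
Title: Bayesian Molecular-Clock Dating of Whole-Genome Duplications from
    Ohnologue Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the absolute age of a whole-genome duplication (WGD)
    event by relaxed molecular-clock dating of concatenated ohnologue pairs
    on a duplicated ("mirrored") gene-tree topology. Provides orthogroup
    conformance screening against the expected paralogy pattern, soft-bounded
    fossil-calibration priors, a birth-death node-age prior with incomplete
    species sampling, geometric-Brownian-motion and independent log-normal
    relaxed clocks, an exact Felsenstein pruning likelihood for amino-acid
    alignments with per-locus normal (gradient/Hessian) approximation, a
    Metropolis-Hastings sampler over node ages and rates, posterior and
    convergence summaries, infinite-sites precision analysis, and a
    synthetic-study generator including a delayed-rediploidization
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
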