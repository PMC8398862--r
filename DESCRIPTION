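Package: polytrait
Title: Polygenic Adaptation of a Quantitative Trait Under Stabilizing
    Selection, Mutation and Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time modelling of rapid adaptation of an additive
    quantitative trait controlled by unlinked diallelic loci. Provides the
    deterministic allele-frequency dynamics under Gaussian stabilizing
    selection with symmetric mutation, short-term approximations for the
    approach of the trait mean to a shifted fitness optimum, a per-locus
    binomial Wright-Fisher simulator with demography schedules (including
    bottlenecks), diffusion-theory predictions (stationary allele-frequency
    density, equilibrium genetic variance, moment dynamics of the adaptive
    phase), and reproducible experiment drivers that compare theory with
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
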