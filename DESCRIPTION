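Package: flockchoice
Title: Discrete Choice Experiment Tools for Livestock Trait Preference Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and estimation tools for discrete choice
    experiments eliciting smallholder farmers' preferences for livestock
    traits. Constructs blocked, effect-coded fractional-factorial choice
    designs with opt-out alternatives and orthogonality/resolution
    diagnostics; validates and filters long-format choice data; simulates
    respondents from a generalized multinomial logit (G-MNL)
    data-generating process with taste and scale heterogeneity; fits
    conditional (multinomial) logit and G-MNL models by maximum simulated
    likelihood with Halton draws; provides the Hausman-McFadden test of
    the independence of irrelevant alternatives, McFadden pseudo-R2,
    Wald odds ratios, and weighted rank-preference indices, together with
    a reproducible design-simulate-estimate-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
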