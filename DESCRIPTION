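Package: gradstate
Title: Brain-State Analysis of Reaction-Time Distributions in Sustained
    Attention Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing gradual-onset continuous performance task
    (gradCPT) reaction times into exGaussian components (mu, sigma, tau) and
    relating them to brain states extracted from network-level fMRI activity.
    Implements the gradCPT press-to-trial assignment algorithm with its
    coherence convention, maximum-likelihood exGaussian fitting with
    negative-skew handling, pairwise maximum-entropy (Ising) modelling of
    binarized network activity with exhaustive energy-landscape analysis
    (local minima and basins define brain states), state-wise pooling of
    reaction times with hemodynamic-lag alignment, and the associated
    statistics (paired t-tests with Hedges' g, Spearman correlations,
    multiple regression, split-half reliability). A synthetic-data module
    co-simulates behavior and binary network dynamics from a planted Ising
    model so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
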