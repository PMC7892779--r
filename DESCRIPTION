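Package: erpperm
Title: Cluster-Based Permutation Tests, Bayes Factors and Effect-Injection
    Power Simulation for ERP Experiments
Version: 0.1.0
Authors@R:
    person("erpperm", "maintainers", email = "erpperm@example.org",
           role = c("aut", "cre"))
Description: Tools for the statistical analysis of event-related potential
    (ERP) experiments with many electrodes and time points: spatio-temporal
    cluster-based permutation tests built on pointwise repeated-measures
    ANOVA or paired t statistics, Jeffreys-Zellner-Siow (JZS) default-prior
    Bayes factors for window-averaged amplitudes, and a single-trial
    effect-injection simulation for estimating the detection power of a
    full analysis pipeline over grids of effect size and sample size.
    Includes a synthetic multi-subject single-trial EEG generator (1/f plus
    alpha background, spatially correlated across a quasi-equidistant
    61-channel montage) emulating a word-by-word reading study, standard
    preprocessing (mastoid re-reference, zero-phase low-pass filtering,
    baseline correction, spherical-spline channel interpolation), and a
    reproducible end-to-end study pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
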