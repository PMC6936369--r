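Package: connsim
Title: Connectome-Based Simulation of Resting-State Dynamics and
    Structure-Function Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to build, transform and analyse directed weighted
    structural connectomes and to simulate resting-state BOLD activity on
    them with a reduced Wong-Wang dynamic mean-field model in the bistable
    regime, coupled to Balloon-Windkessel hemodynamics.  Includes surrogate
    connectome constructions (group averaging, union-mask filtering,
    symmetrization, asymmetrization, single-region hybridization,
    hemispheric mirroring), functional metrics (static functional
    connectivity, sliding-window FC dynamics, functional meta-connectivity,
    predictive power, session similarity, FC lateralization), the
    statistical battery used for group comparisons (Welch tests, Bonferroni
    correction, Cohen's d, percentile bootstrap intervals, normalized
    Mann-Whitney U), a synthetic cohort generator emulating tracer-like and
    diffusion-MRI-like connectomes with multi-session functional data, and
    experiment drivers that quantify how structural manipulations change
    the predictive power for functional connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
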