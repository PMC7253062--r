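Package: wormcolony
Title: Spatial Agent-Based Simulation of C. elegans Colony Life History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, spatially explicit agent-based simulator of clonal
    Caenorhabditis elegans colonies growing on a finite food patch. Worms pass
    through egg, larval, arrested (L1 arrest, dauer diapause) and adult stages on
    a 2D grid carrying a Gaussian food distribution; colony fitness is measured
    as the cumulative yield of dauer dispersal propagules when the patch is
    exhausted. Eleven life-history parameters (fecundity schedule, age-dependent
    mortality, dispersal speeds, stage-specific food consumption, starvation
    limits) define a genotype. The package provides closed-form demography for
    the fecundity and mortality laws, Monte-Carlo and analytic adult lifespan
    estimators, the per-timepoint simulation engine with exact food-conservation
    accounting, and an experiment harness for replicated lifespan-by-dispersal
    parameter sweeps with heatmap summaries, dauer-fraction and food-share
    analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
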