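Package: efcm
Title: Enzyme-Flux Cost Minimization for Kinetic Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates elementary flux modes (EFMs) of a kinetic metabolic
    model, computes the minimal enzyme cost of each mode by convex
    optimization over log-metabolite concentrations (Enzyme Cost
    Minimization), converts enzyme cost into cell growth rate, and analyzes
    rate/yield trade-offs: Pareto fronts, Monod surfaces over external
    substrate concentrations, growth-rate sensitivities to kinetic
    parameters, and reaction-knockout and epistasis screens. Includes
    generators for small, fully specified synthetic model bundles so the
    whole pipeline is testable at toy scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
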