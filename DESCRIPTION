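Package: cbfba
Title: Complex-Balanced Flux Balance Analysis for Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts steady-state metabolic flux distributions by minimizing
    the total absolute activity of reaction complexes (complex-balanced flux
    balance analysis, cbFBA), a constraint-based objective that approximates
    maximizing the number of balanced complexes in a flux distribution.
    Includes the parsimonious FBA (pFBA) baseline, flux variability analysis
    at a fixed optimum, projection-based flux sampling, identification of
    balanced complexes over arbitrary flux spaces, and a battery of
    statistics for comparing predicted fluxes against experimentally
    estimated fluxes with confidence intervals. Models are read from SBML;
    scenario constraints and flux estimates from delimited text. Bundled
    fixtures and synthetic network generators make the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    Matrix,
    jsonlite,
    methods,
    pracma,
    quadprog,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
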