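Package: strainopt
Title: Probabilistic Strain Optimization Under Flux-Capacity Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strain-design optimization for constraint-based metabolic models
    when the outcome of an enzyme up- or down-regulation is uncertain. Flux
    capacities are modelled as probability distributions; a chance-constrained
    mixed-integer linear program (CCOpt) selects reaction interventions that
    maximize a target flux at a user-chosen confidence level, alongside a
    deterministic worst-case counterpart (DetOpt) and a Monte-Carlo sampling
    optimizer (MCOpt). A Monte-Carlo evaluation framework (MCEval) scores any
    intervention set by repeated flux balance analysis under sampled
    capacities. Capacity distributions are estimated either by scaling maximal
    reaction velocities with enzyme fold-change distributions, or from
    elementary flux modes via enzyme-control-flux analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml
Config/testthat/edition: 3
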