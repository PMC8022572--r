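Package: forageEvo
Title: Evolutionary Foraging Agent-Based Model on a Renewable Patch Grid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time agent-based simulator of foragers on a torus grid
    of renewable food patches, for studying the interplay of genetic evolution,
    environmental regime shifts, socially transmitted food sharing, and
    within-lifetime adaptive foraging. Agents carry a heritable foraging
    fraction on a 0.1 grid, store and metabolise food, reproduce within an age
    window, and die of old age, exhaustion, predation, or birth. Scenario
    variants add a permanent regrowth shock, an innovated and vertically
    transmitted sharing practice, and a birth/death vicinity ledger that
    adjusts foraging within a lifetime. The package provides a validated
    configuration layer, replicate experiment runners with strict seed
    discipline, wellbeing and mortality outcome measures, a deterministic
    mechanism-fixture catalogue, and a calibration anchor report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
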