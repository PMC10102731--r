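Package: conceptsym
Title: Common Concepts and Symmetry Spectra for Information-Maximizing
    Grid-World Agents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models memory-limited agents in a pheromone-gradient grid world
    as perception-action loops, optimizes deterministic controllers by
    simulated annealing to capture Shannon information about the initial
    position, merges the resulting agent "concepts" into objective and
    subjective common concepts via information-bottleneck-style functionals,
    and quantifies extrinsic (rotation/reflection/translation) and intrinsic
    (sensor/actuator permutation) symmetries of any concept through exact
    mutual-information utilities. All probability propagation is exact over
    finite joint tables; no sampling estimators are used.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
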