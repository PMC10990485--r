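Package: rotgen
Title: Strategy Models of Rotational Generalisation in Sequence Categorisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how categorisation strategies generalise over
    rotations of abstract sequence concepts. Stimulus sequences (quadruplets)
    are walks on a 4x4 two-dimensional feature grid, each category being a
    fixed triple of compass transition vectors. The package generates the
    complete trial schedules of the four-experiment design (categorisation,
    cross-modal mapping and filler phases), implements the family of
    ideal-observer strategy models (random, non-generalising, signed and
    unsigned one-dimensional trackers, cross-mapped far-transfer variants,
    and the rotation-invariant two-dimensional model), fits them to choice
    data by softmax likelihood over a temperature grid with BIC model
    selection, performs random-effects Bayesian group model comparison with
    between-group Bayes factors, and runs model- and parameter-recovery
    simulations on synthetic softmax-noisy agents. A rotational
    generalisation index (2Dness) and correlation analyses complete the
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
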