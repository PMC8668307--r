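Package: dsmsim
Title: Design Structure Matrix Simulation of Surgical Procedure Duration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a surgical procedure as a design structure matrix (DSM)
    over decomposed activities (surgemes), each with a triangular three-point
    duration estimate, a rework impact and an improvement curve, and each
    pairwise dependency with a rework probability.  Partitions the matrix
    into rework loops (strongly connected components) and active sets,
    simulates total procedure duration by seeded Monte Carlo with
    truncated-geometric rework counts, provides a deterministic
    expected-value analogue, estimates model parameters from annotated
    observation tallies, and analyses rework-risk propagation through the
    geometric-series cumulative risk.  Ships synthetic protocol fixtures for
    a standard and a pediatric laparoscopic cholecystectomy structure and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
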