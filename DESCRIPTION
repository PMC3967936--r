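Package: epilogic
Title: Multi-Valued Logical Models of Gene Regulation on Epithelial Hexagonal Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete, hierarchical modelling framework for epithelial
    patterning. Single cells carry multi-valued logical (Thomas) regulatory
    networks with ordered rule clauses, priority classes and update delays;
    cells are assembled on a cylindrical hexagonal grid and coupled through
    juxtacrine and paracrine integration variables. Provides synchronous and
    asynchronous dynamics, exhaustive stable-state enumeration, state
    transition graphs with attractor (terminal strongly connected component)
    identification and reachability analysis, staged epithelial simulation
    with phase schedules and in-silico perturbations (whole-tissue and clonal
    loss/gain of function), plus two bundled models of Drosophila eggshell
    patterning: a phenomenological fate model and a mechanistic
    EGF/BMP network with roof, floor and operculum readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
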