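Package: popca
Title: Deterministic Cellular-Automaton Models of Single-Species Population
    Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Logical deterministic individual-based cellular automata for
    single-species population growth on a lattice of microhabitats, following
    the excitable-medium (rest / excited / refractory) formalism: free sites
    are colonized from a hexagonal or tripod neighborhood, individuals live one
    iteration, and vacated sites pass through a regeneration state.  Supports
    torus and bounded habitats, full-state limit-cycle detection, closed-form
    unbounded-growth references and the J-shaped geometric model, growth-curve
    phenomenology (plateau onset, transient plateaus, S / double-S / J
    classification, boundary-hit and free-area events), and Monte Carlo
    ensembles over initial placements.  Results are tibbles, with broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
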