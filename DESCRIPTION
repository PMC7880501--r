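Package: evograph
Title: Fixation Probabilities Under Weak Selection on Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary graph theory toolkit for the Birth-death Moran
    process on arbitrary strongly connected weighted (di)graphs. Computes
    neutral fixation probabilities from reproductive values and the
    weak-selection coefficient (the slope of fixation probability in mutant
    fitness at neutrality) from pair coalescence times, in polynomial time.
    Classifies graphs as absolute or relative amplifiers and suppressors of
    weak selection under uniform or temperature initialization, surveys
    complete sets of small connected graphs, provides closed forms for the
    Star, complete bipartite, Cartwheel and Fan families, an exact
    absorbing-Markov-chain solver and Monte Carlo simulator for small graphs,
    a genetic-algorithm search for extremal structures, and deterministic
    parameter scans over Detour and Cartwheel families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
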