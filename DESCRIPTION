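Package: minde
Title: Deterministic Reaction-Diffusion Simulation of the E. coli Min System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates pole-to-pole Min protein (MinD/MinE) oscillations in
    rod-shaped bacteria with a six-species membrane-cytosol reaction-diffusion
    model reduced to one axial dimension on a spherocylinder. Supports
    fixed-length cells, linearly growing cells with dilution and homogeneous
    protein production, and dividing cells with a constricting septum.
    Includes a pattern-analysis layer that collapses trajectories to
    kymographs, classifies patterning regimes (stationary, first- and
    second-order breather modes, travelling-wave mixtures, midcell antinodes),
    estimates oscillation periods by Fourier analysis, locates regime
    transitions by bisection over cell length, and quantifies protein
    partitioning between daughter-cell halves during division.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    tibble,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
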