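Package: slabice
Title: Ice Nucleation Analysis for Slab Simulations and Droplet Freezing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis machinery for studying heterogeneous ice nucleation at
    surfactant-coated water interfaces. Reads and writes slab-geometry
    molecular configurations (extended XYZ and GRO dialects), computes
    Steinhardt bond-orientational order parameters and classifies water
    molecules as ice-like, clusters ice nuclei and profiles their
    centre-of-mass positions across the slab, detects double-diamond and
    hexagonal water cages, derives surface tension and surface pressure from
    pressure-tensor traces, measures monolayer tilt and interfacial-water
    dipole orientations, and evaluates droplet-freezing assays under the
    singular (site-specific) model with Poisson Monte-Carlo confidence
    intervals. Ships synthetic-data generators (ideal ice lattices with
    ice-rule proton decoration, liquid slabs, surrogate monolayers, pressure
    traces, simulated cold-stage assays) so every analysis can be validated
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
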