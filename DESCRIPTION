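Package: molactivity
Title: Molecular Graph Activity Indices and Anti-Tyrosinase Potency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two topological indices of hydrogen-suppressed molecular
    graphs, the external activity D(G) (a normalised sum of distances between
    degree-one vertices) and the internal activity zeta(G) (a normalised sum of
    eccentricity-weighted neighbourhood-irregularity scores over vertices of
    degree greater than one), and combines them in a bivariate cubic polynomial
    model of anti-tyrosinase IC50. Includes constructors for molecular graphs
    from SMILES, SDF and edge lists, an exact interpolating fit of the
    nine-coefficient model with mixed-precision iterative refinement, virtual
    screening by predicted potency, bundled flavonoid reference tables and
    structures, seeded random-graph generators with an independent brute-force
    oracle for property testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
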