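Package: swprop
Title: Small-World Propensity for Binary and Weighted Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-robust quantification of small-world structure in binary
    and weighted networks via the Small-World Propensity (SWP) statistic and
    its companion contribution-to-deviation statistic. Provides generators for
    binary and weighted Watts-Strogatz small-world ensembles with
    distance-decaying edge weights and weight-preserving rewiring, lattice and
    random null models that conserve the observed edge-weight distribution for
    mapping empirical (e.g. brain) networks onto the theoretical model,
    hierarchical-modular and modular benchmark network generators, binary and
    weighted (Onnela, Barrat, Zhang) clustering coefficients, inverse-weight
    characteristic path lengths, and the classical small-world index for
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
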