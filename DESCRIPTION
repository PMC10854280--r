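Package: bncontrol
Title: Modular Decomposition, Canalization, and Phenotype Control of Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synchronous Boolean network models of gene regulation:
    exhaustive attractor enumeration, decomposition into strongly connected
    modules coupled through external parameters, recomposition via the
    semidirect product, edge and node controls with stabilization checks,
    module-by-module control search with a verified global assembly, the
    unique canalizing-layer (extended monomial) decomposition of Boolean
    functions, and canalization-based exclusion of modules from a phenotype
    control search. Networks are read and written in a plain-text
    "target, factors" rule format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
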