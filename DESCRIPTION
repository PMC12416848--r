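Package: ecoassembly
Title: Eco-Evolutionary Assembly of Multi-Interaction Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the assembly of ecological communities under generalized
    Lotka-Volterra dynamics with three interaction types (competition,
    consumer-resource, mutualism) and Type II saturating functional responses.
    Communities grow by speciation with inheritance of interactions or by
    invasion with randomly drawn interactions; candidate species establish only
    if their per-capita growth rate at the extinction threshold is positive,
    and species falling below the threshold or losing all links are pruned.
    Provides linear stability analysis of the community matrix (analytic
    Jacobian and eigenspectrum), network-structure diagnostics (connectance,
    degree entropy, Louvain modularity, and effective increases over
    Erdos-Renyi baselines), and scenario orchestration across replicates with
    tidy trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
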