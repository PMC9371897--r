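Package: nicklattice
Title: Ligation-Induced Stabilization and Reconfiguration of Addressable DNA Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models addressable DNA nanostructure lattices assembled from junction
    and double-crossover motifs as explicit strand/domain/nick graphs, simulates
    stochastic enzymatic nick sealing at a per-nick ligation efficiency, enumerates
    covalent ligation products (linear and circular) and predicts denaturing-gel
    band patterns, estimates ligation efficiency from circular-product fractions,
    classifies strand lock-in and predicts intact-lattice proportions at elevated
    temperature, fits Boltzmann and double-Boltzmann melting curves to survival-rate
    data with Tm defined at survival 0.5, and analyses ligation-induced
    reconfiguration: sub-lattice carving by phosphorylation masks, sheet-to-tube
    closure via sticky-end boundary overhangs, catenated-ring census and chain-mail
    percolation, and an exonuclease-survival rule. Includes a synthetic-data
    generator for survival curves and gel band tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
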