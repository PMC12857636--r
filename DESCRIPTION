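Package: rotapath
Title: Minimum-Energy Threading Pathways of Host-Guest Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps minimum-energy pathways for supramolecular threading and
    assembly with a climbing-image nudged-elastic-band engine over pluggable
    potentials (analytic benchmark surfaces, a coarse-grained host-guest
    threading force field, adapters for external calculators). Converged
    image chains are analysed along a normalized displacement coordinate:
    relative-energy profiles with four-stage segmentation (initialization,
    preparation, activation, stabilization) and barrier extraction, geometric
    descriptors of macrocycle opening and hydrogen bonding, grid-based
    noncovalent-interaction (reduced density gradient) analysis on
    promolecular densities, and a steric/electrostatic/quantum energy
    decomposition. Reads and writes extended XYZ trajectories and Gaussian
    cube files; results come back as tibbles with tidy(), glance() and
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
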