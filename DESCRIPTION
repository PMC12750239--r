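Package: bilayr
Title: Structural and Dynamic Analysis of Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular trajectories of lipid bilayers in
    orthorhombic periodic boxes: number and charge density profiles along
    the membrane normal, headgroup-peak bilayer thickness, packing density
    (reciprocal area per lipid), lateral diffusion coefficients via the
    Einstein relation, deuterium order parameters of acyl chains,
    transmembrane electrostatic potential by double integration of the
    Poisson equation, and intra- and intermolecular chain distances from
    radial distribution functions. Includes a synthetic bilayer-trajectory
    generator with analytically known ground truth for every observable,
    readers and writers for GRO and PDB coordinate files, and a
    configuration-driven pipeline producing tidy observable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
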