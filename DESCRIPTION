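Package: oxymap
Title: Simulation of Chronic Tumor Hypoxia from Vascular Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the spatial distribution of chronic hypoxia in tumor
    cross-sections from binary maps of the perfused vasculature. A coupled
    oxygen/cell-density reaction-diffusion system is solved on a uniform
    grid with no-flux boundaries until the relative hypoxic fraction is
    stationary. Hypoxia is quantified with relative thresholds (HP2.5, HP5,
    HP10) by the area method and by virtual polarographic needle-electrode
    tracks under uniform, random and radial placement strategies; sampling
    strategies are compared through variance-components analysis. Radiation
    response under heterogeneous oxygenation is computed with a
    linear-quadratic survival model scaled by the oxygen modification
    factor. Includes a seeded synthetic vascular-map generator for cohort
    studies when histological images are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
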