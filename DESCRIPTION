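Package: retinapop
Title: Virtual Populations of the Retinal Vasculature with Network Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates anatomically plausible virtual retinal vasculatures from
    the central retinal vessels down to the three macular capillary plexuses,
    and links their structure to function. Arterial and venous trees are grown
    over the temporal retina by staged constrained constructive optimization
    seeded from a statistical shape model of the major temporal arcades;
    capillary beds for the superficial, intermediate and deep plexuses are
    synthesized from Voronoi tessellations and wired to the trees. Blood flow
    is solved on the resulting network with Poiseuille resistances and a
    diameter-dependent effective viscosity law. The package computes OCTA-style
    morphometrics (vessel area/skeleton density, diameter and complexity
    indices, fractal dimension, intervessel distance, Horton-Strahler orders),
    runs virtual cohorts with structure-function correlation analysis, and
    provides variance-based (Sobol) sensitivity analysis and uncertainty
    quantification of the hemodynamic closure parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    interp,
    FNN,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
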