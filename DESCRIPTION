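Package: slabnr
Title: Slab-Model Analysis of Specular Neutron Reflectometry from
    Supported Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing specular neutron reflectometry of
    supported lipid bilayers at the solid-liquid interface.  Computes
    coherent scattering-length densities of lipid head and tail regions
    from elemental composition, including labile-proton exchange with
    H2O/D2O solvent mixtures; evaluates exact slab-stack reflectivity by
    the Abeles optical matrix method with Nevot-Croce interfacial
    roughness and Gaussian resolution smearing; builds area-coupled
    symmetric three-layer and one-layer-plus-vesicle bilayer
    parameterizations; and co-refines one structural model against
    several water contrasts simultaneously, with multistart bounded
    optimisation and residual-bootstrap uncertainties.  A seeded
    synthetic-data generator emulates time-of-flight contrast-variation
    measurements so that the full analysis chain can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
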