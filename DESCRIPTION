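Package: rhodmap
Title: Descriptor Computation and Chemical-Space Mapping for Dirhodium(II) Paddlewheel Catalysts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes steric and electronic descriptors for Rh2L4 paddlewheel
    complexes (unbound and carbene-bound) from XYZ geometries and
    quantum-chemistry property records: metal-metal distance, donor angles,
    ligand bite angle, carbene angle, frontier-orbital quantities, partial
    charges, a distance-weighted steric volume, an eight-helium steric probe,
    and a carbene coordination energy. Assembles descriptor tables and builds
    Pearson correlation maps, PCA catalyst maps with explained variance and
    projection loss, diversity-selected screening sets, and overlays of
    experimental screening outcomes. Ships a synthetic fixture generator for
    idealized paddlewheel geometries and covariance-controlled descriptor
    tables, and a command-line interface binding the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
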