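Package: rnmap
Title: Ramachandran Numbers and Multi-Angle Pictures for Protein Backbones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compact per-residue description of protein and peptoid backbone
    conformation via the Ramachandran number, a scalar collapse of the
    (phi, psi) dihedral pair onto [0, 1], together with its signed variant
    for achiral backbones. Reads single- and multi-model PDB files, computes
    backbone dihedrals from coordinates, and builds stackable products from
    conformational ensembles and trajectories: per-residue maps, per-model
    histogram series, deviation maps, and residue-type or neighbor-conditioned
    histogram stacks, rendered with secondary-structure and chirality
    colormaps. Includes an ideal-geometry backbone builder (internal to
    Cartesian) for generating synthetic ensembles and for relating the
    Ramachandran number to radius of gyration, end-to-end distance and
    backbone handedness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
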