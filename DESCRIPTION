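Package: npcsim
Title: Ground-Truth Simulation of Structurally Variable Nuclear Pore Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes ground-truth coordinate datasets of structurally
    variable nuclear pore complexes (NPCs) for benchmarking single-molecule
    localization microscopy (SMLM) analysis software. Label sites of one
    rotational unit are expanded into an s-fold symmetric node cloud, varied
    geometrically (radius, height, twist, tilt, shift, elongation, symmetry),
    and deformed irregularly-but-coherently by relaxing per-ring spring
    systems under spatially correlated random forces sampled from a Gaussian
    process with a radial basis function kernel. Annotated ground-truth
    features are extracted by 3D circle and ellipse fitting, and coordinates
    are exported as CSV tables ready for downstream photophysics simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    bio3d,
    knitr
Config/testthat/edition: 3
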