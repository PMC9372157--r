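Package: orbitmorph
Title: Orbit-Shape Morphometrics and Plate Biomechanics of Archosauromorphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links the shape of the orbital opening in archosauromorph skulls
    to biomechanical performance. Provides parametric generators for orbit
    outlines (circular, elliptical, constricted keyhole and wedge
    morphologies) and covariate-linked synthetic populations; a standardized
    cross-hair landmarking protocol (8 fixed landmarks plus 56 semi-landmarks)
    with TPS file input and output; generalized Procrustes superimposition and
    principal component morphospaces; a plane-stress finite-element solver for
    rectangular plates pierced by orbit-shaped holes, with quasi-homothetic
    load scaling and stress concentration factors; thin-plate-spline
    performance heatmaps over morphospace; deformation-space quantification of
    undeformed/deformed landmark pairs; and squared-change parsimony mapping
    of shape distances onto a phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools
Config/testthat/edition: 3
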