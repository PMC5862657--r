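Package: ssbctf
Title: Single-Sideband Contrast Transfer Correction for Ewald Sphere
    Curvature in Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complex (single-sideband) contrast transfer function correction
    for defocused phase-contrast electron micrographs. At sufficient defocus
    the two pseudo-Friedel-related Fourier components of a particle separate
    physically in the image, so each can be extracted on its own and inserted
    into the 3D transform at its true position on the curved Ewald sphere
    rather than on a flat central section. The package provides the scalar
    transfer-function optics, the separation/box-size geometry rules, the
    sideband-overlap insertion weighting, the multi-sector half-plane
    correction with soft masking, a weak-phase image simulator (single-
    component fringe phantoms and curved-sphere projections of 3D phantoms),
    Fourier-space 3D insertion with Wiener normalisation, Fourier shell
    correlation, and a two-map validation that determines the curvature
    direction and hence the absolute hand of the specimen. MRC2014 volumes
    and stacks and plain TSV particle tables are read and written natively,
    and a small command-line driver exposes the main stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
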