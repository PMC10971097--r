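Package: dectangio
Title: Dual-Energy Micro-CT Angiography Toolkit
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dual-energy micro-CT post-mortem angiography with a
    barium sulfate contrast agent: bundled X-ray mass attenuation tables,
    filtered polychromatic tube spectrum models, digital phantoms (contrast
    tube and branching vessel trees) with polychromatic projection
    simulation and filtered back-projection, image-domain three-material
    decomposition into volume-fraction maps, virtual monoenergetic image
    synthesis at the barium K-edge, contrast-to-noise-based spectral pair
    optimization, and vessel segmentation with maximum-inscribed-sphere
    local diameter mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
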