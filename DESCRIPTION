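Package: gzp6dose
Title: TG-43U1 Dosimetry and Dose-Matrix Superimposition for GZP6
    Cobalt-60 Brachytherapy Sources
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for high-dose-rate brachytherapy dosimetry of the GZP6
    cobalt-60 afterloading unit following the AAPM TG-43U1 formalism:
    line-source geometry function, dose-rate constant, radial dose function
    and 2D anisotropy function extraction, quintic radial fits, and dose
    reconstruction by table interpolation.  Multi-pellet source dose
    distributions are derived from a single-pellet dose matrix by a
    shift-weight-sum superimposition algorithm, with isodose contour
    extraction on Cartesian dose grids.  A synthetic single-pellet kernel
    with exact TG-43 multiplicative structure supports validation without
    any radiation-transport code.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
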