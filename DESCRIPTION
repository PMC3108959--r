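Package: ifpsim
Title: Interstitial Fluid Pressure and Flow in Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state interstitial fluid transport in solid tumors modelled
    as Darcy flow in a rigid porous medium with Starling transcapillary
    filtration sources and lymphatic sinks. Provides closed-form spherically
    symmetric solutions (uniform, necrotic-core and embedded-in-normal-tissue
    tumors), a conservative finite-volume solver on 1-D radial grids, a
    voxel-based 3-D finite-volume solver for arbitrary tumor masks, and
    analysis tools for the critical tumor radius and critical necrotic radius.
    Profiles are exported as CSV, 3-D fields as legacy VTK, and run summaries
    as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
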