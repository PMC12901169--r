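Package: ptxsar
Title: Worst-Case SAR Measurement Error from Directional Coupler Directivity in Parallel-Transmit MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the worst-case underestimation of local specific
    absorption rate (SAR) and total forward power in multi-channel MRI
    transmit systems caused by the finite directivity of directional
    couplers.  The measurement error is expressed as a complex error matrix
    acting on the excitation vector; virtual-observation-point (VOP) sets
    are transformed into their as-measured counterparts, and the maximum
    ratio of actual to measured SAR over all complex excitations and all
    reference-plane phase offsets is computed via a semidefinite relaxation
    with a rank-one extraction certificate.  Includes S-parameter passivity
    analysis, a brute-force sampling oracle for verification, synthetic
    array/VOP generators, Touchstone and JSON I/O, and an end-to-end
    analysis pipeline with tidy outputs and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
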