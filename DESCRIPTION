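Package: redoxmip
Title: Constraint-Based Inference of Redox-Regulated Signaling and
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint inference of a cell-state-specific Boolean signaling
    network and a thermodynamically constrained metabolic flux network
    from fold-change multi-omics measurements, formulated as a
    mixed-integer program over binary protein/edge/enzyme states and
    continuous fluxes and metabolite ratios.  Includes flux balance
    analysis utilities that attribute fractional contributions of
    reactions to the maximal production of a target cofactor (for
    example NADPH), a synthetic-network generator with planted ground
    truth, and an exhaustive brute-force oracle for end-to-end
    verification of the optimization core.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
SystemRequirements: Python (>= 3.8) with scipy, for the bundled
    HiGHS solver bridge
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
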