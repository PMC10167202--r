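Package: osteodyn
Title: Tumor-Coupled Bone Remodeling Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and stability analyser for power-law
    osteoclast-osteoblast bone remodeling dynamics coupled to Gompertz
    tumor growth. Implements three tumor-coupling variants of the
    Komarova basic-multicellular-unit model: tumor-modulated production
    and removal rates (nine scenarios), a tumor paracrine power-law
    factor, and tumor-dependent autocrine/paracrine exponents. Provides
    closed-form nontrivial steady states, analytic Jacobians with
    Routh-Hurwitz classification and eigenvalue taxonomy,
    stability-region scans, and adaptive time integration of cell
    numbers, tumor burden, and bone mass, plus trajectory diagnostics
    for limit cycles, damped oscillations, divergence, and collapse.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
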