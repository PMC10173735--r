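Package: ctldyn
Title: Cell-Cycle-Resolved Modelling of CTL-Melanoma Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary differential equation modelling of cytotoxic T
    lymphocyte (CTL) activity inside B16F10 melanoma tumors, resolving the
    tumor cell cycle into G1 and S-G2-M compartments.  The model couples
    CTL killing and IFN-gamma mediated G1 arrest to CTL influx, intratumoral
    expansion and death, and to exhaustion driven by the immune checkpoints
    LAG3, HAVCR2 and PDCD1/CD274.  Includes maximum-likelihood fitting of
    checkpoint model variants to multi-modal time-series observables
    (multistart Latin hypercube + bounded quasi-Newton), AIC model
    comparison, practical-identifiability analysis by adaptive Metropolis
    sampling with parallel hierarchical chains, and a synthetic-data
    generator emulating the study design (tumor volumes, cryosection counts,
    pooled microarray expression) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    lhs,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
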