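Package: actintread
Title: Steady-State Reaction-Diffusion Model of Treadmilling Actin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic 1D steady-state model of the treadmilling actin
    network that forms the lamellipodium and lamellum of migrating cells.
    Filaments are nucleated at the leading edge, grow against the membrane
    load through a thermal-ratchet polymerization rate, are stochastically
    capped, age through ATP hydrolysis and competitive ADF/cofilin versus
    tropomyosin binding, debranch, and depolymerize from their minus ends.
    The coupled integro-differential equations for the F-actin density,
    filament length distribution, minus-end density, depolymerization source
    density, and the diffusive G-actin profile are closed by a fixed-point
    iteration on the leading-edge monomer concentration. Confined (convergence
    zone at the rear boundary) and rearwards-unconfined networks are
    supported, together with semi-analytical and brute-force ensemble
    verification oracles and parameter-scan drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
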