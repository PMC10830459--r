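Package: inlandn2o
Title: Nitrous Oxide Dynamics in Stream-River-Lake-Reservoir Networks
Version: 0.1.0
Authors@R: person("Aquatic Biogeochemistry", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of nitrous oxide (N2O) emissions from
    inland waters. Routes daily runoff and terrestrial nitrogen loads
    (nitrate, ammonium, dissolved and particulate organic N) through a
    gridded stream-river-lake-reservoir network with a scale-adaptive
    hillslope/subnetwork/main-channel scheme, solves a per-element
    dissolved-N2O mass balance (advection, in-water production from
    nitrification and denitrification, rain deposition, reduction to N2,
    and air-water exchange that permits net atmospheric uptake), and runs
    the four-stage simulation protocol (equilibrium, spin-up, natural-flow
    and dam-managed transients) with factorial attribution experiments,
    load-perturbation uncertainty ensembles, and dynamic agricultural
    emission factors at country and global level. A synthetic-data module
    generates every required input so the full pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
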