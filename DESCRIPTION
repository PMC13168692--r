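Package: beemorph
Title: Geometric Versus 3D-Model Morphometrics and Heat Budgets for Bees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating insect body surface area and volume from
    linear caliper measurements under classical solid-shape assumptions
    (cylinder head, spherical mesosoma, cylinder-plus-cone metasoma), for
    measuring the same quantities empirically from calibrated triangulated
    surface meshes, and for quantifying the disagreement between the two
    (percent error, mean signed error, paired tests). Includes log-log
    allometric scaling of surface area on volume with isometry tests, a
    steady-state heat budget over 20-50 degrees C that partitions metabolic,
    evaporative, longwave radiative (Stefan-Boltzmann) and residual convective
    heat transfer per body tagma, propagation of surface-area measurement
    error through the budget, and a deterministic synthetic-specimen generator
    (analytic solid meshes, perturbed specimens with known truth, paired
    measurement cohorts, thermal-response coefficient sets) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
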