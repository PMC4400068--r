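Package: gaspref
Title: Thermal Phenotyping and Compositional Analysis of Nitrous Oxide
    Self-Administration
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studies of voluntary nitrous oxide (N2O) inhalation in
    rats phenotyped by total calorimetry.  Converts infrared beam-break logs
    from a three-compartment self-administration apparatus into chamber
    residence times, assembles 44-h dyad compositions, and analyses the
    N2O-versus-control preference ratio with a from-scratch log-ratio GEE
    (generalized estimating equations) engine with cluster-robust sandwich
    covariance.  Includes direct plus indirect calorimetry heat-balance
    partitioning (core temperature, heat production via the Lusk oxygen
    energy equivalent, dry and evaporative heat loss), z-score based
    extreme-group screening, exact two-sided Fisher tests, compositional
    utilities (zero replacement, centered geometric means, ternary
    coordinates), and a synthetic-cohort generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
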