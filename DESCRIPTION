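Package: topdownmem
Title: Native Top-Down Mass Spectrometry Analysis of Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for native top-down mass spectrometry of alpha-helical
    membrane proteins: intact-mass inference from multi-charge peak series
    with detergent- and phospholipid-adduct ladder detection, theoretical
    b/y fragment generation under disulfide constraints, fragment-to-peak
    matching across charge states, and charge-normalized fragmentation
    landscapes (per-site abundance profiles, sequence coverage and tags,
    residue-pair cleavage heat maps, transmembrane-topology enrichment).
    Includes a seeded simulator of MS1 charge-state spectra with adduct
    ladders under a laser-power detergent-removal model and of MS2 fragment
    spectra driven by residue-pair cleavage propensities, helix-stability
    weights and mobile-proton availability, with ground-truth records for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
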