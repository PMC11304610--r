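Package: aortamimic
Title: Lattice-Reinforced Metamaterial Design and Tensile Analysis for Aortic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing 3D-printable lattice-reinforced metamaterials
    that mimic the mechanics of the aortic wall, and for analysing uniaxial
    tensile tests of the printed specimens. Procedurally generates chain,
    knitted, diamond-crystal and Miura-ori (origami) unit cells, tessellates
    them into flat matrix slabs or conformally onto tubular vessel walls,
    computes lattice volume fractions and writes STL. Implements the tensile
    processing chain (engineering stress/strain, curve alignment, zero-phase
    Butterworth filtering, incremental elastic modulus over a configurable
    test-duration window), batch summaries (mean, standard deviation,
    coefficient of variation) and Welch one-sided comparisons against bundled
    literature values for healthy and aneurysmal aortas. A seeded synthetic
    generator emulates strain-softening polymers, strain-stiffening
    tissue-like materials and composites whose matrix ruptures before the
    lattice, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
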