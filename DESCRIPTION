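Package: npcharge
Title: Charge and Hydrophobicity Profiling of Nuclear Transport Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based physicochemical profiling of nuclear transport
    receptors, cargo proteins and nucleoporins, and a screened-Coulomb model
    of the electrostatic contribution to translocation through the nuclear
    pore complex (NPC). Computes net charge at fixed pH from ionization
    constants, isoelectric points, per-residue hydrophobicity and polarity
    profiles over a registry of empirical scales, an aggregate hydrophobicity
    axis by principal component analysis, hierarchical clustering and
    heat-map exports, a two-dimensional charge/hydrophobicity property space
    with regime classification, Debye-Hueckel screened electrostatic energy
    predictions for translocating particles, and a reproducible synthetic
    sequence generator for receptor-like, cargo-like, FG-nucleoporin-like
    and proteome-background cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
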