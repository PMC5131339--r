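Package: umscreen
Title: Unfolding Mutation Screen for In Silico Saturation Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete in-silico saturation-mutagenesis scan of a protein
    structure. Converts per-mutation free-energy changes (ddG, kcal/mol) into
    unfolding propensities on a two-state sigmoidal unfolding curve, assembles
    a position-by-amino-acid propensity matrix, summarises it as per-residue
    foldability and critical residues, renders standard and hierarchically
    clustered unfolding heat maps, exports residue attributes for 3D structure
    colouring, and validates computed propensities against experimental ones
    via match matrices, percent matching and a fit score. Includes seeded
    synthetic generators (toy helix structures, ddG tables with planted
    critical residues, noisy experimental/computed propensity pairs) so the
    whole pipeline runs end-to-end without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
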