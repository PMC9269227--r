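Package: ivscreen
Title: Inverse Virtual Screening with Decoy-Normalised Docking Affinities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target fishing for small molecules by inverse virtual screening:
    prepare a panel of protein structures (cleaning, binding-site definition,
    docking-box construction), dock query compounds and ten property-matched
    structurally dissimilar decoys, normalise each best affinity V0 by the mean
    decoy affinity VR into the dimensionless V = V0/VR, retain targets with
    affinity below -7.5 kcal/mol and V above 0.75, and rank per-compound top
    targets and cross-compound consensus targets grouped by UniProt accession.
    Includes geometric pose auditing (hydrogen bonds, pi-pi stacking, salt
    bridges), a deterministic replay backend for recorded affinity tables, and
    a synthetic-data module with planted true targets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    bio3d,
    ChemmineR,
    ChemmineOB,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
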