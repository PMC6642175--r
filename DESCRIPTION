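Package: edgotype
Title: Structural Interactome Edgotyping and Dispensable Interaction Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds residue-resolved structural interactomes from chain
    coordinates and sequence-to-chain alignments, maps disease and
    non-disease missense mutations onto binding interfaces, classifies
    mutation edgotypes by interface geometry and by binding free energy
    change (ddG) thresholding, and estimates the completely dispensable
    fraction of a protein-protein interactome with Bayesian
    ratio-of-proportions confidence intervals. Includes a synthetic-world
    generator with known ground truth so the entire pipeline can be
    exercised and validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
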