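Package: turnpath
Title: Turn-Driven Alpha-to-Beta Transition Analysis for Peptide Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of short
    peptides undergoing an alpha-helix to beta-hairpin transition, built around
    the 12-residue N-terminal fragment of alpha-synuclein (alpha-syn12,
    MDVFMKGLSKAK). Provides Kabsch superposition and Calpha RMSD, RMSD-cutoff
    (Daura/GROMOS) conformational clustering, geometric hydrogen-bond and
    beta-turn annotation, a discrete turn/hydrogen-bond reaction coordinate with
    two-dimensional free-energy surfaces and basin detection, turn-versus-
    hydrogen-bond mechanism statistics (occurrence tables, conditional
    probabilities, transition-path counts), and a synthetic backbone-trajectory
    generator with programmed folding mechanisms for validation without
    molecular-dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
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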