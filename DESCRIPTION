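Package: ligmodes
Title: Classification of Protein-Ligand Binding Modes from Structures and
    Dose-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify small-molecule binding modes at a shared
    protein pocket, developed around the allosteric antagonist site at the
    GluN1/GluN2B N-terminal-domain dimer interface of the NMDA receptor.
    Computes residue-panel minimum-distance interaction fingerprints of
    bound or docked ligand poses and groups them into binding-mode classes
    by agglomerative hierarchical clustering; measures interface-cavity
    volumes on a grid bounded by inclusion and exclusion spheres, together
    with ligand-occupied and cross-occupied ("common pocket") volumes;
    superposes structures by the Kabsch algorithm and reports C-alpha RMSD;
    and fits Hill inhibition models to electrophysiological dose-response
    data to estimate IC50, Hill coefficient, maximal inhibition and
    mutant/wild-type IC50 ratios. Includes seeded generators for synthetic
    receptors, two-archetype pose sets, analytic-volume pocket fixtures and
    Hill-model dose-response datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    ChemmineR,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
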