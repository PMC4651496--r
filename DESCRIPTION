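Package: epimapr
Title: Antibody Epitope Mapping from NMR Shift Perturbation, Docking
    Ensembles and Sequence Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping conformational antibody epitopes on small
    antigens such as the EF-hand parvalbumin fish allergens. Computes
    per-residue chemical shift perturbations (CSP) from amide 1H/15N shift
    tables, classifies significantly perturbed and exchange-broadened
    (disappeared) residues, fits 15N R1/R2 relaxation decays, derives
    per-residue contact frequencies from rigid-body docking pose ensembles
    using a heavy-atom distance criterion, computes Shrake-Rupley solvent
    accessibility, annotates structures with residue scores in the B-factor
    column, and reports Clustal-style conservation of epitope residues
    across a protein family to rationalize antibody cross-reactivity. A
    synthetic-data module generates every input with a machine-readable
    manifest of planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
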