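Package: molcharge
Title: Partial Atomic Charge Prediction for Small Molecules by Per-Element
    Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-atom partial charges (units of e) for small organic
    molecules from a fixed 61-slot molecular-graph feature encoding and one
    regression model per chemical element.  Provides native readers for PDB,
    SDF V2000 and a SMILES subset, distance-based bond perception, ring
    perception by depth-first search, linear path-fragment fingerprints with
    Tanimoto similarity for dataset-diversity analysis, united-atom hydrogen
    merging and net-charge redistribution for molecular-dynamics use, a
    synthetic molecule generator with a deterministic electronegativity-
    equalization charge oracle, and a command-line interface tying the
    pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    caret,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
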