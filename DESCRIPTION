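Package: distfluct
Title: Distance-Fluctuation Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of protein internal dynamics from
    conformational ensembles (molecular-dynamics trajectories or synthetic
    ensembles): distance-fluctuation (DF) matrices over C-alpha atoms,
    local-fluctuation (LF) profiles, pairwise F-test comparison of two
    systems' DF matrices with region summarization, rigid-body superposition
    and loop RMSD series, open/closed conformational-state classification,
    Shrake-Rupley solvent-accessible surface area of catalytic-site residues,
    native-contact persistence and salt-bridge tracking.  Includes a
    seed-reproducible synthetic two-chain ensemble generator with a two-state
    (closed/open) gate loop so the full pipeline can be exercised and
    validated against analytic ground truth without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
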