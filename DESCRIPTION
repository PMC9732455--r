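Package: molforge
Title: AI-Assisted De Novo Design Toolkit for Kinase Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven toolkit reproducing an AI-assisted hit-to-candidate
    de novo design workflow for kinase inhibitors: ligand-based reverse target
    prediction over a protein-ligand interaction network using six fingerprint
    families and six bit-vector similarity measures with rank-score aggregation;
    a character-level LSTM SMILES language model with transfer-learning
    fine-tuning, temperature sampling and MOSES-style generation metrics; a
    retrosynthesis-associated fragment-based synthetic feasibility (RAFSF)
    score built from BRICS fragment/bond frequency spaces; a lead-like triage
    funnel (property windows, PAINS/structural alerts, novelty, feasibility,
    pluggable toxicity predicates); kinase-panel selectivity scoring from
    rescaled docking scores; and a Bennett acceptance ratio (BAR) free-energy
    estimator over tabulated lambda-window samples. Standard cheminformatics
    primitives (SMILES parsing, fingerprints, BRICS, PAINS catalogs) are
    delegated to an RDKit helper invoked as an external batch tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with the rdkit package, available as
    'python' on the PATH (configurable via options(molforge.python=)).
Config/testthat/edition: 3
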