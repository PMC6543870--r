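Package: tauramd
Title: Interaction-Fingerprint Analysis of Ligand Dissociation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of random acceleration molecular dynamics (RAMD)
    ligand-dissociation trajectories for drug-target residence time analysis.
    Extracts per-frame protein-ligand interaction fingerprints from trajectory
    frames, groups them into hydrogen-bond, aromatic, ionic and apolar contact
    categories, truncates the bound-state part of each trajectory under
    configurable contact-loss rules, and aggregates contact occurrences into
    compound-level feature matrices. Estimates relative residence times from
    replica-structured egress-time statistics and scales them to experimental
    off-rates. Provides the accompanying machine-learning protocol: constrained
    train/test splitting, ridge and support vector regression with grid-search
    hyperparameter selection, repeated-split evaluation with MAE and Q2F3
    scoring, and Gaussian-mixture clustering of dissociation mechanisms with
    AIC model selection. Includes synthetic-data generators for toy
    protein-ligand complexes, fingerprint streams and egress-time samples.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    e1071,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
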