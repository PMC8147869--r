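Package: promsets
Title: Structured Multi-Target and Single-Target Compound Datasets from Screening Assays
Version: 0.1.0
Authors@R:
    person("promsets", "developers", email = "promsets@example.org", role = c("aut", "cre"))
Description: Derives structured compound datasets for promiscuity analysis from
    biological screening data. Provides assay and compound curation (hit-rate,
    antitarget, interference and inconsistency filters), ternary activity-matrix
    construction, promiscuity-degree and test-frequency computation, assembly of
    experimentally complete groups of one multi-target (MT) compound with
    corresponding single-target (ST) compounds, random and nearest-neighbor
    reduced-set generation, an MT-versus-ST classification benchmark with
    balanced accuracy, a tab-delimited dataset dialect reader/writer, and a
    synthetic screening-world generator with planted ground truth for testing
    every stage. Molecule handling (SMILES canonicalization, circular
    fingerprints, substructure matching) and the benchmark classifiers are
    delegated to bundled RDKit and scikit-learn helper scripts run through the
    system Python.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with rdkit and scikit-learn available as
    'python' on the PATH (or via option 'promsets.python')
Config/testthat/edition: 3
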