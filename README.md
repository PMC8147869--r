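# promsets

Structured multi-target / single-target compound datasets from biological
screening assays.

## The problem

Compounds that are active against several targets (multi-target compounds,
MT-CPDs, also called promiscuous compounds) are central to polypharmacology
and to the study of structure–promiscuity relationships. Meaningful analysis
and machine-learning prediction of promiscuity require datasets in which the
multi-target label is *experimentally certain*: a compound may look
single-target simply because it was never tested against the other targets.
Screening databases (e.g. PubChem BioAssay) are the one source that reports
both positive and negative assay outcomes and per-compound test frequencies,
which makes such certainty possible — after heavy curation.

`promsets` implements that curation and dataset-construction pipeline as a
tested, reusable R package, for computational and medicinal chemists who
want to build or audit MT/ST compound collections:

1. **Assay curation** — keep native, target-mapped, human-target assays;
   drop antitarget assays (hERG, CYP, P-gp, ...), assays with hit rate
   > 2 %, cytotoxicity readouts, and assays with inconsistent
   compound–target annotations; optionally restrict to biochemical assays.
2. **Compound screening** — flag and remove interference compounds: PAINS
   and empirical-liability substructures, colloidal aggregators, firefly
   luciferase (FLuc) inhibitors.
3. **Activity matrix** — collapse assay records into a ternary
   compound × target matrix with outcomes in {active, inactive, untested};
   no potency threshold is applied.
4. **Promiscuity grouping** — the promiscuity degree of compound *c* is
   PD(*c*) = |{t : outcome(c, t) = active}|, its test frequency
   n_tested(*c*) = |{t : outcome(c, t) ≠ untested}|. MT compounds
   (PD ≥ 5, or PD ≥ 3 as a control) are paired, per active target, with a
   single-target compound (PD = 1) that is active against that target and
   *experimentally confirmed inactive* against the group's remaining
   targets. Each ST compound is used at most once; groups are complete:
   every member has a recorded outcome for every group target.
5. **Reduced sets** — 50 % random group removal, and iterative
   nearest-neighbor removal: repeatedly take the most similar group pair
   (maximum Tanimoto similarity over cross-group ST members) and remove
   the member with the higher similarity to its next most similar group,
   until 25 % of groups are gone; repeat on MT-compound similarity for
   another 25 %.
6. **Prediction benchmark** — MT-vs-ST classification with RBF-SVM, 1-NN
   (Tanimoto distance) and random forest on 2048-bit Morgan fingerprints;
   per trial the ST class is down-sampled to the MT count, split into
   stratified halves, and scored by balanced accuracy
   (sensitivity + specificity)/2 over 10 trials.
7. **Synthetic worlds** — a generator of complete screening worlds
   (assays, real enumerable molecules, activity records) with planted
   ground truth for every stage, used by the test suite.

Datasets are read and written in a tab-delimited dialect with columns
`NostereoAromaticSMILES`, `is_MT`, `group`, `cid`, `target_ids`,
`n_tested`, `random_removal_set`, `nn_removal_set`.

Molecule handling (SMILES canonicalization, Morgan fingerprints, SMARTS
matching) runs through RDKit, and the benchmark classifiers through
scikit-learn, via bundled helper scripts executed with the system `python`
(see `SystemRequirements`); everything else is R.

## Worked example

```r
library(promsets)

cfg   <- world_preset("tiny", seed = 3)      # 40 compounds, 6 targets
world <- generate_world(cfg)
world
#> <synthetic_world: 40 compounds, 6 targets, 6 assays, 222 records>

retained <- filter_assays(world$assays, curation_config())$retained
mat <- build_activity_matrix(
  world$records[world$records$assay_id %in% retained, ])
mat
#> <activity_matrix: 40 compounds x 6 targets, 76 active / 146 inactive calls>

smiles <- setNames(world$compounds$smiles, world$compounds$compound_id)
ds <- assemble_groups(mat, pd_min = 5, smiles = smiles)
dataset_summary(ds)
#> MT compounds: 8
#> ST compounds: 21
#> Groups: 8
#> Targets: 6
#> ST per MT: 1:3 2:1 3:1 4:2 5:1
verify_completeness(ds, mat)
#> completeness: OK (0 violations)

ds$groups[[1]]$st_members      # one confirmed ST compound per MT target
#>     T001     T002     T004     T005     T006
#> "C00011" "C00004" "C00013" "C00003" "C00021"

red <- nn_removal(ds, fingerprint(smiles))   # iterative NN removal
dataset_summary(red$reduced)
#> MT compounds: 4
#> ST compounds: 8
#> Groups: 4
#> Targets: 6
#> ST per MT: 1:2 2:1 4:1
```

The summary reads: 8 multi-target compounds (PD ≥ 5) could each be paired
with at least one confirmed single-target compound (21 ST compounds in
total; three groups got one ST member, one group five). After
nearest-neighbor removal exactly half the groups remain. Writing
`write_dataset_tsv(ds, "dataset.tsv")` emits the eight-column deposited
dialect; `read_dataset_tsv()` round-trips it.

A command-line interface covers the same pipeline:

```sh
exec/promsets simulate --preset tiny --seed 3 --out world/
exec/promsets group --records world/records.tsv --smiles world/compounds.tsv \
    --pd-min 5 --out dataset.tsv
exec/promsets verify --tsv dataset.tsv
exec/promsets reduce --tsv dataset.tsv --method nn --out reduced.tsv
exec/promsets benchmark --tsv dataset.tsv --trials 10 --seed 7
```

## Package layout

- `R/` — data model + TSV dialect (`activity-data.R`), structure handling
  (`chem.R`), assay curation (`assay-curation.R`), interference screening
  (`compound-screening.R`), activity matrix and group assembly
  (`grouping.R`), reduced sets (`reduction.R`), benchmark (`benchmark.R`),
  synthetic worlds (`synthetic-data.R`), CLI (`cli.R`).
- `inst/python/` — RDKit and scikit-learn helper scripts.
- `vignettes/promiscuity-datasets.Rmd` — methods: model, parameters,
  what the synthetic generator does and does not emulate, design choices.
- `tests/testthat/` — unit, property and acceptance suites.
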