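---
title: "Building multi-target / single-target compound datasets from screening assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multi-target / single-target compound datasets from screening assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(promsets)
```

## The model

Promiscuity analysis asks whether a compound's activity against multiple
targets is a real, structure-driven property. The statistic at the center
of this package is the **promiscuity degree**

$$\mathrm{PD}(c) = \bigl|\{\, t : \mathrm{outcome}(c, t) = \text{active} \,\}\bigr|,$$

computed on a ternary compound × target activity matrix with outcomes in
{active, inactive, untested}. The companion quantity is the **test
frequency** $n_\mathrm{tested}(c)$, the number of targets with any
recorded outcome. The PD of a compound is only meaningful relative to its
test frequency: an apparently single-target compound may simply be
untested elsewhere. Screening repositories are the one data source that
reports negative results, so both quantities are observable — after
curation, because screening data are rife with artifacts.

The pipeline's central construct is the **compound group**: one
multi-target compound (MT, $\mathrm{PD} \ge k$ with $k = 5$ as the
significant-promiscuity threshold and $k = 3$ as a control) together
with, for each of its active targets, at most one **single-target
compound** (ST, $\mathrm{PD} = 1$) that is active against that target and
*experimentally confirmed inactive* against all remaining targets of the
group. By construction every group is **complete**: each member has a
recorded outcome for every group target, so no PD value can be
underestimated by missing tests and no ST label can be a false negative
of under-testing. Each ST compound is used in at most one group; MT
compounds for which no qualifying ST compound remains are omitted.

## Assumptions and scope

* Activity is consumed as binary active/inactive outcome calls; no
  potency thresholds are applied and no potency values are stored.
  Qualitative annotations are sufficient for promiscuity analysis.
* Curation context (target mapping, species, antitarget membership,
  cytotoxicity readouts) arrives as flags or identifier lists on the
  assay records; the package does not resolve taxonomies or target
  families itself, and it does not talk to any database service — it
  consumes already-exported tables.
* Conflicting annotations (a compound active *and* inactive against one
  target) are resolved at assay granularity by default: every assay
  contributing to a conflicted pair is removed
  (`resolve_inconsistencies(..., "assay")`). A `"pair"` granularity that
  drops only the conflicting records is available. After resolution, the
  matrix builder treats any surviving conflict as an error rather than
  applying a silent precedence rule.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_hit_rate` | 0.02 | assays with active fraction above 2 % are removed as artifact-prone |
| `assay_formats` | both | `"biochemical"` restricts to the higher-confidence biochemical subset; running both configurations yields the mixed and biochemical dataset pair |
| `pd_min` | 5 | MT threshold; 3 is the conventional control |
| `fingerprint radius / n_bits` | 2 / 2048 | hashed circular (Morgan) substructure fingerprints, binary occurrence — the de-facto standard descriptor in this literature |
| `fraction_per_pass` | 0.25 | NN removal quota per pass, fixed against the *original* group count, so two passes remove exactly half the groups |
| `n_trials` | 10 | benchmark repetitions; per trial the ST class is down-sampled to the MT count and split 50/50 stratified |

Classifier settings (RBF-SVM with unit cost, 1-nearest-neighbor with
Tanimoto/Jaccard distance, 100-tree random forest) are deliberately
plain defaults: the benchmark exists to compare dataset *variants*, not
to maximize accuracy, and only directional claims (original ≥ random
removal ≥ NN removal) are asserted by the test suite.

## Algorithmic choices where the procedure is underdetermined

Several steps of the published procedure admit more than one reading;
the package fixes each deterministically:

* **ST candidate selection.** Among qualifying unused candidates for a
  target, the one with the highest test frequency wins (most confirmed
  inactivity evidence), ties broken by lowest compound id.
* **MT processing order.** PD descending, then compound id ascending —
  high-PD compounds have the rarest ST requirements and get first pick
  under the global ST-uniqueness constraint. The test suite verifies
  that whenever an MT compound ends up without ST members, no qualifying
  unused candidate existed at its processing time.
* **Inter-group similarity.** "Most similar ST compounds" is read as the
  *maximum* cross-group ST–ST Tanimoto similarity (max-linkage);
  mean-linkage is available via `linkage = "mean"`. MT-mode similarity
  is the Tanimoto similarity of the two MT members.
* **NN removal tie-breaks.** Tied top pairs: lexicographically smallest
  (group id, group id); tied next-best similarities: remove the larger
  group id. With these rules the procedure is a pure function of the
  similarity values — invariant to input order, byte-stable across runs.
* **Per-pass quota.** Both passes remove `ceiling(0.25 * n0)` groups
  where `n0` is the *original* group count; the final dataset therefore
  holds exactly half the original groups (up to ceiling), which is what
  fixes the quota convention.
* **TSV dialect.** The deposited column set is
  `NostereoAromaticSMILES, is_MT, group, cid, target_ids, n_tested,
  random_removal_set, nn_removal_set`. The `target_ids` cell carries the
  *compound's own* active-target list — the full (semicolon-joined)
  target set on the MT row, the single assigned target on each ST row.
  This is the only encoding under which a file round-trips field-by-field
  (with the alternative "every row repeats the group list" encoding, the
  target→ST assignment would be unrecoverable whenever a middle target
  lacks an ST member). The reader accepts `;`, `,` or `|` separators and
  liberal boolean spellings; the writer is canonical (`;`,
  `True`/`False`, groups renumbered `0..n-1`).

## The synthetic world generator

`generate_world()` emulates the *structure* of a curated screening
export: per-target assays with substance counts, compounds with real
(enumerable) structures, and one activity record per tested
compound–target pair, negatives included. Ground truth for every
downstream stage is returned alongside.

* **Structures.** Each analog family is one core template from a library
  of 161 RDKit-validated ring systems; analogs share the scaffold and one
  fixed substituent and vary the second substitution site ("shared
  scaffold, one substituent change"). All emitted molecules are valid and
  globally distinct by construction; the test suite re-validates the
  grammar against RDKit.
* **Activity.** Each compound receives a planted PD drawn from
  `pd_distribution` and an active-target set of that size; non-active
  pairs are tested (inactive) with probability `test_coverage`. Two
  optional structural plants mirror properties of the real data: a
  higher `st_test_coverage` reproduces the observation that ST
  compounds are tested more broadly than MT compounds, and
  `family_target_coherence` makes an analog family share its home
  target set — the series-level structure–activity coherence that makes
  similar compound groups redundant, which is precisely what iterative
  NN removal exploits. With `separate_mt_families = TRUE` families are
  class-pure, planting structurally separable MT/ST classes.
* **Violations.** Knobs plant, in known quantities: high-hit-rate assays
  (5 % actives), antitarget assays (extra flagged assays on dedicated
  antitarget identifiers), active+inactive conflicts (a second,
  contradicting record in a different assay of the same target), and
  deny-listed interference compounds. The curation attrition report must
  recover these counts exactly.

What the generator does **not** emulate — and therefore what a green
test does not establish: real PubChem assay-size and target-family
distributions, realistic hit-rate dispersion, activity cliffs,
stereochemistry (structures are emitted achiral), tautomerism, or
medicinal-chemistry-like scaffold frequency. Passing tests certify the
*procedure* (curation arithmetic, completeness guarantees, removal
algorithms, protocol determinism), not any quantitative property of the
original screening extraction; published full-scale counts are
snapshot-dependent and out of scope.

## Numerical and degenerate-input behavior

* Tanimoto similarity on two empty fingerprints is a contract error
  (cannot arise for valid molecules — any molecule with one heavy atom
  sets at least one bit).
* `compute_hit_rate` refuses assays with `n_tested = 0`.
* NN removal requires at least 4 groups; when only two groups remain
  and one must still be removed, both next-best similarities are
  $-\infty$ and the larger group id is removed (the documented
  tie-break).
* Balanced accuracy requires both classes in the reference labels.
* An empty dataset is representable end-to-end: header-only TSV, empty
  summary, empty feature table.
* All stochastic operations (`random_removal`, `run_trials`,
  `generate_world`) take explicit integer seeds and restore the caller's
  RNG state; identical seeds give byte-identical results.

## Verifying against the deposited reference datasets

`verify_deposition()` checks a local copy of the three deposited dataset
files (mixed PD ≥ 5, biochemical PD ≥ 5, biochemical PD ≥ 3) against
their published composition — 2858/15839, 1242/6629 and 3468/11793
MT/ST compounds respectively — plus the structural invariants the reader
enforces (unique cids, exactly one MT row per group, per-group target
consistency). The files are an external open-access download and are not
bundled; the corresponding acceptance test states exactly what to
provide and fails informatively otherwise. Because the spelling of
booleans and list separators inside the deposit is not printed anywhere,
the liberal reader should be reconciled against the actual files the
first time verification mode is used.

## Known limitations

* The exact fingerprint used for NN removal and prediction in the source
  study is not published; magnitudes of the benchmark are therefore not
  comparable, only the removal-effect ordering.
* ST uniqueness is enforced per selection run; the mixed and biochemical
  datasets are independent runs and may share ST compounds.
* Reproduction of the original deposited group memberships is not
  attempted (the original sampling order is unknown); only the
  procedure's guarantees are reproduced.
* The python bridge spawns one interpreter per batched call; on
  extremely large inputs a persistent process would be faster. At the
  scales this package targets (thousands of compounds) each call is
  seconds.
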