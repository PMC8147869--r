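# Synthetic world generator: determinism, structure grammar, planted
# ground truth, fixture suite.

test_that("the whole scaffold/substituent grammar is RDKit-valid and distinct", {
  templates <- promsets:::scaffold_templates()
  subs <- promsets:::substituent_library()
  # every template probed with three representative substituent pairs
  probes <- list(c("[H]", "[H]"), c("F", "C(=O)O"), c("OC", "C#N"))
  smiles <- unlist(lapply(templates, function(t) {
    vapply(probes, function(p) sprintf(t, p[1], p[2]), character(1))
  }))
  can <- canonicalize_smiles(smiles)   # errors on any invalid SMILES
  expect_length(unique(can), length(templates) * length(probes))
})

test_that("generate_structures yields valid, distinct, reproducible molecules", {
  cfg <- world_config(n_compounds = 10L, n_scaffold_families = 2L,
                      analogs_per_family = 5L, seed = 4L)
  smi <- generate_structures(cfg)
  expect_length(smi, 10)
  expect_length(unique(smi), 10)
  expect_length(unique(canonicalize_smiles(smi)), 10)
  expect_identical(smi, generate_structures(cfg))

  # demanding more analogs than a family can enumerate is a config error
  over <- world_config(n_compounds = 100L, n_scaffold_families = 2L,
                       analogs_per_family = 21L)
  expect_error(generate_structures(over), "exceed enumerable")
})

test_that("generate_world is deterministic and self-consistent", {
  cfg <- world_preset("tiny", 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)

  # emitted records, when matrixed, equal the planted outcome table
  m <- build_activity_matrix(w1$records)
  expect_identical(m$outcome[rownames(w1$truth$outcome)[
                     rownames(w1$truth$outcome) %in% m$compounds],
                   colnames(w1$truth$outcome)[
                     colnames(w1$truth$outcome) %in% m$targets]],
                   w1$truth$outcome[rownames(w1$truth$outcome) %in% m$compounds,
                                    colnames(w1$truth$outcome) %in% m$targets])
  # pairs outside the record-derived matrix are untested in truth
  missing_t <- setdiff(colnames(w1$truth$outcome), m$targets)
  expect_true(all(w1$truth$outcome[, missing_t] == 0L))
})

test_that("pipeline PD equals planted PD in violation-free worlds", {
  for (s in c(1, 9)) {
    w <- cached_world("tiny", s)
    m <- build_activity_matrix(w$records)
    prof <- promiscuity_profile(m)
    expect_identical(prof$pd, unname(w$truth$pd[prof$compound_id]))
  }
})

test_that("degenerate configurations behave as forced", {
  # all compounds single-target: no MT class at any threshold
  cfg <- world_config(n_compounds = 30L, n_targets = 6L,
                      pd_distribution = c("1" = 1.0),
                      n_scaffold_families = 4L, analogs_per_family = 10L,
                      seed = 2L)
  w <- generate_world(cfg)
  m <- build_activity_matrix(w$records)
  expect_true(all(promiscuity_profile(m)$pd == 1L))
  expect_length(assemble_groups(m, 5L)$groups, 0)

  # full coverage: every compound tested on every target
  cfg2 <- world_config(n_compounds = 20L, n_targets = 5L,
                       pd_distribution = c("1" = 0.8, "3" = 0.2),
                       test_coverage = 1.0, n_scaffold_families = 4L,
                       analogs_per_family = 10L, seed = 3L)
  w2 <- generate_world(cfg2)
  m2 <- build_activity_matrix(w2$records)
  expect_true(all(promiscuity_profile(m2)$n_tested == 5L))

  # infeasible PD support
  expect_error(world_config(n_targets = 4L,
                            pd_distribution = c("1" = 0.5, "6" = 0.5)),
               "exceeds n_targets")
  expect_error(world_config(pd_distribution = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
})

test_that("planted curation violations are recovered from the attrition world", {
  w <- cached_world("attrition", 3)
  truth <- w$truth
  cfg <- curation_config(antitarget_ids = truth$antitarget_ids,
                         assay_formats = "biochemical")
  res <- filter_assays(w$assays, cfg)
  rep <- res$report
  expect_equal(rep$removed[rep$rule == "antitarget"],
               length(truth$antitarget_assays))
  expect_equal(rep$removed[rep$rule == "hit_rate"],
               length(truth$high_hit_rate_assays))
  expect_equal(detect_inconsistent_assays(w$records, res$retained),
               truth$inconsistent_assays)
  flags <- flag_compounds(w$compounds, truth$rule_sets)
  expect_setequal(names(flags)[lengths(flags) > 0], truth$liability)
})

test_that("more single-target mass means more ST compounds per MT group", {
  mean_st <- function(p1, seed) {
    cfg <- world_config(n_compounds = 120L, n_targets = 8L,
                        pd_distribution = c("1" = p1, "5" = 1 - p1),
                        test_coverage = 0.9, n_scaffold_families = 8L,
                        analogs_per_family = 16L, seed = seed)
    m <- build_activity_matrix(generate_world(cfg)$records)
    ds <- assemble_groups(m, 5L)
    if (length(ds$groups) == 0) return(NA_real_)
    mean(lengths(lapply(ds$groups, `[[`, "st_members")))
  }
  diffs <- vapply(1:4, function(s) mean_st(0.85, s) - mean_st(0.5, s),
                  numeric(1))
  expect_true(all(diffs > 0))
})

test_that("make_fixture_suite writes loadable worlds with ground truth", {
  out <- withr::local_tempdir()
  make_fixture_suite(out, seed = 1L)
  expect_setequal(list.dirs(out, recursive = FALSE, full.names = FALSE),
                  c("tiny", "conflict", "liability", "analog", "separable"))
  tiny <- file.path(out, "tiny")
  cmp <- read.delim(file.path(tiny, "compounds.tsv"))
  expect_lte(nrow(cmp), 50)
  rec <- read.delim(file.path(tiny, "records.tsv"), colClasses = "character")
  truth <- jsonlite::read_json(file.path(tiny, "truth.json"))
  expect_equal(sort(names(truth$pd)), sort(cmp$compound_id))
  # conflict world: detector finds exactly the planted assays
  crec <- read.delim(file.path(out, "conflict", "records.tsv"),
                     colClasses = "character")
  ctruth <- jsonlite::read_json(file.path(out, "conflict", "truth.json"))
  found <- detect_inconsistent_assays(
    activity_records(crec$compound_id, crec$target_id, crec$assay_id,
                     crec$outcome))
  expect_equal(found, unlist(ctruth$inconsistent_assays))
})

test_that("the command-line interface round-trips simulate/group/verify", {
  out <- withr::local_tempdir()
  promsets_cli(c("simulate", "--preset", "tiny", "--seed", "2",
                 "--out", out))
  expect_true(file.exists(file.path(out, "records.tsv")))
  ds_path <- file.path(out, "dataset.tsv")
  capture.output(promsets_cli(c("group", "--records",
                                file.path(out, "records.tsv"),
                                "--pd-min", "5", "--out", ds_path,
                                "--smiles", file.path(out, "compounds.tsv"))))
  expect_true(file.exists(ds_path))
  txt <- capture.output(promsets_cli(c("verify", "--tsv", ds_path)))
  expect_true(any(grepl("invariants: OK", txt)))
})
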