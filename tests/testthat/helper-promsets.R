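# Shared test helpers: cached synthetic worlds, hand-built fingerprints and
# datasets (no python needed for pure-logic tests).

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(preset, seed = 1L) {
  key <- paste(preset, seed)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(world_preset(preset, seed))
  }
  .world_cache[[key]]
}

world_smiles <- function(world) {
  stats::setNames(world$compounds$smiles, world$compounds$compound_id)
}

.fp_cache <- new.env(parent = emptyenv())

cached_fps <- function(world, key) {
  if (is.null(.fp_cache[[key]])) {
    .fp_cache[[key]] <- fingerprint(world_smiles(world))
  }
  .fp_cache[[key]]
}

# fingerprint object from explicit bit indices (0-based), bypassing rdkit
fp <- function(bits, n_bits = 64L) {
  structure(list(bits = as.integer(sort(bits)), n_bits = as.integer(n_bits),
                 radius = 2L),
            class = "fingerprint")
}

# minimal valid group / dataset builders
make_group <- function(id, mt, targets, st, n_tested = NULL) {
  members <- c(mt, unname(st))
  if (is.null(n_tested)) {
    n_tested <- stats::setNames(rep(length(targets), length(members)), members)
  }
  compound_group(id, mt, targets, st, n_tested)
}

# dataset of n single-ST groups with distinct targets/compounds
make_plain_dataset <- function(n, pd_threshold = 5L) {
  groups <- lapply(seq_len(n), function(i) {
    make_group(i - 1L, sprintf("M%03d", i),
               sprintf("T%03d_%d", i, 1:5),
               stats::setNames(sprintf("S%03d", i), sprintf("T%03d_1", i)))
  })
  cids <- unlist(lapply(groups, function(g) c(g$mt_compound, unname(g$st_members))))
  promiscuity_dataset(groups, pd_threshold = pd_threshold,
                      smiles = stats::setNames(rep("c1ccccc1", length(cids)), cids))
}

# small random activity matrix built from explicit records
random_matrix <- function(n_compounds, n_targets, p_active = 0.2,
                          p_inactive = 0.5) {
  cids <- sprintf("c%02d", seq_len(n_compounds))
  tids <- sprintf("t%02d", seq_len(n_targets))
  rec <- expand.grid(compound_id = cids, target_id = tids,
                     stringsAsFactors = FALSE)
  u <- stats::runif(nrow(rec))
  rec$outcome <- ifelse(u < p_active, "active",
                        ifelse(u < p_active + p_inactive, "inactive", NA))
  rec <- rec[!is.na(rec$outcome), , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)
  build_activity_matrix(
    activity_records(rec$compound_id, rec$target_id,
                     paste0(rec$target_id, "_A1"), rec$outcome))
}

expect_same_dataset <- function(a, b) {
  expect_equal(length(a$groups), length(b$groups))
  ga <- a$groups[order(vapply(a$groups, `[[`, integer(1), "group_id"))]
  gb <- b$groups[order(vapply(b$groups, `[[`, integer(1), "group_id"))]
  for (i in seq_along(ga)) {
    expect_identical(ga[[i]]$group_id, gb[[i]]$group_id)
    expect_identical(ga[[i]]$mt_compound, gb[[i]]$mt_compound)
    expect_identical(ga[[i]]$target_set, gb[[i]]$target_set)
    expect_identical(ga[[i]]$st_members, gb[[i]]$st_members)
    expect_identical(ga[[i]]$n_tested[order(names(ga[[i]]$n_tested))],
                     gb[[i]]$n_tested[order(names(gb[[i]]$n_tested))])
  }
  expect_identical(a$smiles[order(names(a$smiles))],
                   b$smiles[order(names(b$smiles))])
  expect_identical(sort(a$removal_marks$random_removal_set),
                   sort(b$removal_marks$random_removal_set))
  expect_identical(sort(a$removal_marks$nn_removal_set),
                   sort(b$removal_marks$nn_removal_set))
}
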