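# Synthetic screening-world generator. Emits complete worlds -- assay
# metadata, compound structures, activity records -- with planted ground
# truth for every downstream stage: per-compound promiscuity degree, the
# ternary outcome table, scaffold-family membership, liability compounds,
# and per-rule curation violations (high-hit-rate assays, antitarget
# assays, inconsistent compound-target pairs).
#
# Structures are real enumerable molecules: each scaffold family is one
# core template from a pre-validated library, and analogs enumerate
# substituent pairs on that core, so fingerprint similarity within a
# family exceeds similarity between families and the chemistry-dependent
# stages (reduction, benchmark) are exercised realistically. The template
# x substituent grammar is RDKit-validated by the test suite; world
# generation itself is pure R and fast.

# 161 core templates, two substitution slots each, ordered so consecutive
# indices differ in ring system (single/fused cores first, then two-ring
# cores interleaved by first-ring type). Validated: every template x
# substituent-pair combination (161 x 231 = 37191 molecules) parses in
# RDKit and all canonical structures are globally distinct.
scaffold_templates <- function() c(
  "c1cc(%s)ccc1%s", "c1cc(%s)cnc1%s",
  "c1cc(%s)c2ccccc2c1%s", "c1cc(%s)c2ncccc2c1%s",
  "c1cc(%s)c2[nH]ccc2c1%s", "c1cc(%s)sc1%s",
  "c1cc(%s)oc1%s", "c1cc(%s)c2occc2c1%s",
  "c1cc(%s)c2sccc2c1%s", "C1CC(%s)CCN1%s",
  "c1cc(%s)c2nc[nH]c2c1%s", "O=C1Nc2ccc(%s)cc2C1%s",
  "C1CC(%s)OCC1%s", "C1CC(%s)CCC1%s",
  "c1nc(%s)c2ccc(%s)cc2n1", "c1cc(%s)c2nccnc2c1%s",
  "c1cc(%s)ccc1c1ccc(%s)cc1", "c1cc(%s)cnc1c1ccc(%s)cn1",
  "c1cc(%s)sc1c1cc(%s)cs1", "c1cc(%s)oc1c1cc(%s)co1",
  "C1CC(%s)CCC1C1CCC(%s)CC1", "c1cc(%s)ccc1c1ccc(%s)cn1",
  "c1cc(%s)cnc1c1cc(%s)cs1", "c1cc(%s)sc1c1cc(%s)co1",
  "c1cc(%s)oc1C1CCC(%s)CC1", "C1CC(%s)CCC1CC1CCC(%s)CC1",
  "c1cc(%s)ccc1c1cc(%s)cs1", "c1cc(%s)cnc1c1cc(%s)co1",
  "c1cc(%s)sc1C1CCC(%s)CC1", "c1cc(%s)oc1Cc1cc(%s)co1",
  "C1CC(%s)CCC1CCC1CCC(%s)CC1", "c1cc(%s)ccc1c1cc(%s)co1",
  "c1cc(%s)cnc1C1CCC(%s)CC1", "c1cc(%s)sc1Cc1cc(%s)cs1",
  "c1cc(%s)oc1CC1CCC(%s)CC1", "C1CC(%s)CCC1OC1CCC(%s)CC1",
  "c1cc(%s)ccc1C1CCC(%s)CC1", "c1cc(%s)cnc1Cc1ccc(%s)cn1",
  "c1cc(%s)sc1Cc1cc(%s)co1", "c1cc(%s)oc1CCc1cc(%s)co1",
  "C1CC(%s)CCC1NC1CCC(%s)CC1", "c1cc(%s)ccc1Cc1ccc(%s)cc1",
  "c1cc(%s)cnc1Cc1cc(%s)cs1", "c1cc(%s)sc1CC1CCC(%s)CC1",
  "c1cc(%s)oc1CCC1CCC(%s)CC1", "C1CC(%s)CCC1C(=O)C1CCC(%s)CC1",
  "c1cc(%s)ccc1Cc1ccc(%s)cn1", "c1cc(%s)cnc1Cc1cc(%s)co1",
  "c1cc(%s)sc1CCc1cc(%s)cs1", "c1cc(%s)oc1Oc1cc(%s)co1",
  "C1CC(%s)CCC1S(=O)(=O)C1CCC(%s)CC1", "c1cc(%s)ccc1Cc1cc(%s)cs1",
  "c1cc(%s)cnc1CC1CCC(%s)CC1", "c1cc(%s)sc1CCc1cc(%s)co1",
  "c1cc(%s)oc1OC1CCC(%s)CC1", "C1CC(%s)CCC1OCc1ccc(%s)cc1",
  "c1cc(%s)ccc1Cc1cc(%s)co1", "c1cc(%s)cnc1CCc1ccc(%s)cn1",
  "c1cc(%s)sc1CCC1CCC(%s)CC1", "c1cc(%s)oc1Nc1cc(%s)co1",
  "C1CC(%s)CCC1OCc1ccc(%s)cn1", "c1cc(%s)ccc1CC1CCC(%s)CC1",
  "c1cc(%s)cnc1CCc1cc(%s)cs1", "c1cc(%s)sc1Oc1cc(%s)cs1",
  "c1cc(%s)oc1NC1CCC(%s)CC1", "C1CC(%s)CCC1OCc1cc(%s)cs1",
  "c1cc(%s)ccc1CCc1ccc(%s)cc1", "c1cc(%s)cnc1CCc1cc(%s)co1",
  "c1cc(%s)sc1Oc1cc(%s)co1", "c1cc(%s)oc1C(=O)c1cc(%s)co1",
  "C1CC(%s)CCC1OCc1cc(%s)co1", "c1cc(%s)ccc1CCc1ccc(%s)cn1",
  "c1cc(%s)cnc1CCC1CCC(%s)CC1", "c1cc(%s)sc1OC1CCC(%s)CC1",
  "c1cc(%s)oc1C(=O)C1CCC(%s)CC1", "C1CC(%s)CCC1OCC1CCC(%s)CC1",
  "c1cc(%s)ccc1CCc1cc(%s)cs1", "c1cc(%s)cnc1Oc1ccc(%s)cn1",
  "c1cc(%s)sc1Nc1cc(%s)cs1", "c1cc(%s)oc1S(=O)(=O)c1cc(%s)co1",
  "C1CC(%s)CCC1C=CC1CCC(%s)CC1", "c1cc(%s)ccc1CCc1cc(%s)co1",
  "c1cc(%s)cnc1Oc1cc(%s)cs1", "c1cc(%s)sc1Nc1cc(%s)co1",
  "c1cc(%s)oc1S(=O)(=O)C1CCC(%s)CC1", "c1cc(%s)ccc1CCC1CCC(%s)CC1",
  "c1cc(%s)cnc1Oc1cc(%s)co1", "c1cc(%s)sc1NC1CCC(%s)CC1",
  "c1cc(%s)oc1OCc1ccc(%s)cc1", "c1cc(%s)ccc1Oc1ccc(%s)cc1",
  "c1cc(%s)cnc1OC1CCC(%s)CC1", "c1cc(%s)sc1C(=O)c1cc(%s)cs1",
  "c1cc(%s)oc1OCc1ccc(%s)cn1", "c1cc(%s)ccc1Oc1ccc(%s)cn1",
  "c1cc(%s)cnc1Nc1ccc(%s)cn1", "c1cc(%s)sc1C(=O)c1cc(%s)co1",
  "c1cc(%s)oc1OCc1cc(%s)cs1", "c1cc(%s)ccc1Oc1cc(%s)cs1",
  "c1cc(%s)cnc1Nc1cc(%s)cs1", "c1cc(%s)sc1C(=O)C1CCC(%s)CC1",
  "c1cc(%s)oc1OCc1cc(%s)co1", "c1cc(%s)ccc1Oc1cc(%s)co1",
  "c1cc(%s)cnc1Nc1cc(%s)co1", "c1cc(%s)sc1S(=O)(=O)c1cc(%s)cs1",
  "c1cc(%s)oc1OCC1CCC(%s)CC1", "c1cc(%s)ccc1OC1CCC(%s)CC1",
  "c1cc(%s)cnc1NC1CCC(%s)CC1", "c1cc(%s)sc1S(=O)(=O)c1cc(%s)co1",
  "c1cc(%s)oc1C=Cc1cc(%s)co1", "c1cc(%s)ccc1Nc1ccc(%s)cc1",
  "c1cc(%s)cnc1C(=O)c1ccc(%s)cn1", "c1cc(%s)sc1S(=O)(=O)C1CCC(%s)CC1",
  "c1cc(%s)oc1C=CC1CCC(%s)CC1", "c1cc(%s)ccc1Nc1ccc(%s)cn1",
  "c1cc(%s)cnc1C(=O)c1cc(%s)cs1", "c1cc(%s)sc1OCc1ccc(%s)cc1",
  "c1cc(%s)ccc1Nc1cc(%s)cs1", "c1cc(%s)cnc1C(=O)c1cc(%s)co1",
  "c1cc(%s)sc1OCc1ccc(%s)cn1", "c1cc(%s)ccc1Nc1cc(%s)co1",
  "c1cc(%s)cnc1C(=O)C1CCC(%s)CC1", "c1cc(%s)sc1OCc1cc(%s)cs1",
  "c1cc(%s)ccc1NC1CCC(%s)CC1", "c1cc(%s)cnc1S(=O)(=O)c1ccc(%s)cn1",
  "c1cc(%s)sc1OCc1cc(%s)co1", "c1cc(%s)ccc1C(=O)c1ccc(%s)cc1",
  "c1cc(%s)cnc1S(=O)(=O)c1cc(%s)cs1", "c1cc(%s)sc1OCC1CCC(%s)CC1",
  "c1cc(%s)ccc1C(=O)c1ccc(%s)cn1", "c1cc(%s)cnc1S(=O)(=O)c1cc(%s)co1",
  "c1cc(%s)sc1C=Cc1cc(%s)cs1", "c1cc(%s)ccc1C(=O)c1cc(%s)cs1",
  "c1cc(%s)cnc1S(=O)(=O)C1CCC(%s)CC1", "c1cc(%s)sc1C=Cc1cc(%s)co1",
  "c1cc(%s)ccc1C(=O)c1cc(%s)co1", "c1cc(%s)cnc1OCc1ccc(%s)cc1",
  "c1cc(%s)sc1C=CC1CCC(%s)CC1", "c1cc(%s)ccc1C(=O)C1CCC(%s)CC1",
  "c1cc(%s)cnc1OCc1ccc(%s)cn1", "c1cc(%s)ccc1S(=O)(=O)c1ccc(%s)cc1",
  "c1cc(%s)cnc1OCc1cc(%s)cs1", "c1cc(%s)ccc1S(=O)(=O)c1ccc(%s)cn1",
  "c1cc(%s)cnc1OCc1cc(%s)co1", "c1cc(%s)ccc1S(=O)(=O)c1cc(%s)cs1",
  "c1cc(%s)cnc1OCC1CCC(%s)CC1", "c1cc(%s)ccc1S(=O)(=O)c1cc(%s)co1",
  "c1cc(%s)cnc1C=Cc1ccc(%s)cn1", "c1cc(%s)ccc1S(=O)(=O)C1CCC(%s)CC1",
  "c1cc(%s)cnc1C=Cc1cc(%s)cs1", "c1cc(%s)ccc1OCc1ccc(%s)cc1",
  "c1cc(%s)cnc1C=Cc1cc(%s)co1", "c1cc(%s)ccc1OCc1ccc(%s)cn1",
  "c1cc(%s)cnc1C=CC1CCC(%s)CC1", "c1cc(%s)ccc1OCc1cc(%s)cs1",
  "c1cc(%s)ccc1OCc1cc(%s)co1", "c1cc(%s)ccc1OCC1CCC(%s)CC1",
  "c1cc(%s)ccc1C=Cc1ccc(%s)cc1", "c1cc(%s)ccc1C=Cc1ccc(%s)cn1",
  "c1cc(%s)ccc1C=Cc1cc(%s)cs1", "c1cc(%s)ccc1C=Cc1cc(%s)co1",
  "c1cc(%s)ccc1C=CC1CCC(%s)CC1")

substituent_library <- function() c(
  "[H]", "F", "Cl", "Br", "I", "C", "CC", "CCC", "C(C)C", "OC", "O", "N",
  "NC", "C#N", "C(F)(F)F", "[N+](=O)[O-]", "C(=O)O", "C(=O)N",
  "S(=O)(=O)N", "CO", "C=C")

# An analog family is one core template with one substituent slot fixed
# per family; analogs enumerate the other slot ("shared scaffold, one
# substituent change"). One family per template keeps all molecules
# globally distinct.
family_capacity <- function() length(substituent_library())

#' Synthetic world configuration
#'
#' The stated world for the synthetic screening generator. Defaults
#' describe a modest screening campaign: a dozen protein targets with two
#' assays each, 200 compounds dominated by single-target actives with a
#' promiscuous tail, dense-but-incomplete test coverage, and sub-percent
#' hit rates. Violation knobs (liability compounds, antitarget and
#' high-hit-rate assays, inconsistent annotations) default to zero.
#'
#' @param n_targets Number of screening targets.
#' @param n_assays_per_target Assays per target (>= 2 needed to plant
#'   inconsistent annotations).
#' @param n_compounds Number of compounds.
#' @param pd_distribution Named numeric vector: probability of each planted
#'   promiscuity degree (names are PD values, support within
#'   `1..n_targets`, probabilities summing to 1).
#' @param test_coverage Probability that a non-active (compound, target)
#'   pair is tested (and recorded inactive).
#' @param st_test_coverage Optional separate coverage for PD = 1 compounds;
#'   setting it above `test_coverage` plants the higher-ST-test-frequency
#'   contrast. `NULL` means equal coverage.
#' @param base_hit_rate Hit-rate ceiling used when padding assay substance
#'   counts; kept below the curation cutoff for non-violation assays.
#' @param n_scaffold_families Number of analog families (<= 161, the core
#'   template library size; one family per core).
#' @param analogs_per_family Maximum compounds per family (<= 21, the
#'   single-slot enumeration capacity).
#' @param separate_mt_families If TRUE, families are class-pure: multi-target
#'   compounds draw structures from one block of families and single-target
#'   compounds from a disjoint block, planting structurally separable
#'   classes and family-level nearest-neighbor structure.
#' @param family_target_coherence Probability that a compound inherits its
#'   analog family's home target (set) instead of a uniform draw. Nonzero
#'   values plant the structure-activity coherence of real chemical series
#'   (a series hits the same targets), which makes similar compound groups
#'   genuinely redundant and is what iterative nearest-neighbor removal
#'   exploits. 0 disables (targets independent of structure).
#' @param frac_liability Fraction of compounds planted as interference
#'   compounds (deny-listed, half aggregator / half FLuc inhibitor).
#' @param frac_antitarget_assays,frac_high_hit_rate_assays Fractions (of
#'   the main assay count) of extra violation assays planted.
#' @param n_inconsistent_pairs Number of planted active+inactive conflicts.
#' @param seed Integer seed; identical configurations generate identical
#'   worlds.
#' @return A list of class `world_config`; `frac_mt` (probability mass at
#'   PD >= 2) is derived and attached.
#' @export
world_config <- function(n_targets = 12L, n_assays_per_target = 2L,
                         n_compounds = 200L,
                         pd_distribution = c("1" = 0.75, "2" = 0.08,
                                             "3" = 0.06, "4" = 0.04,
                                             "5" = 0.04, "6" = 0.02,
                                             "7" = 0.01),
                         test_coverage = 0.8, st_test_coverage = NULL,
                         base_hit_rate = 0.01,
                         n_scaffold_families = 12L, analogs_per_family = 20L,
                         separate_mt_families = FALSE,
                         family_target_coherence = 0,
                         frac_liability = 0, frac_antitarget_assays = 0,
                         frac_high_hit_rate_assays = 0,
                         n_inconsistent_pairs = 0L, seed = 1L) {
  pdv <- as.integer(names(pd_distribution))
  if (anyNA(pdv) || any(pdv < 1)) {
    stop("pd_distribution must be named by integer PD values >= 1",
         call. = FALSE)
  }
  if (abs(sum(pd_distribution) - 1) > 1e-8) {
    stop("pd_distribution probabilities must sum to 1", call. = FALSE)
  }
  if (max(pdv) > n_targets) {
    stop("pd_distribution support exceeds n_targets", call. = FALSE)
  }
  if (n_scaffold_families > length(scaffold_templates())) {
    stop("at most ", length(scaffold_templates()), " scaffold families",
         call. = FALSE)
  }
  stopifnot(test_coverage >= 0, test_coverage <= 1,
            is.null(st_test_coverage) ||
              (st_test_coverage >= 0 && st_test_coverage <= 1),
            family_target_coherence >= 0, family_target_coherence <= 1,
            frac_liability >= 0, frac_liability <= 1,
            analogs_per_family >= 1, n_compounds >= 1, n_targets >= 1)
  cfg <- list(n_targets = as.integer(n_targets),
              n_assays_per_target = as.integer(n_assays_per_target),
              n_compounds = as.integer(n_compounds),
              pd_distribution = pd_distribution,
              frac_mt = sum(pd_distribution[pdv >= 2]),
              test_coverage = test_coverage,
              st_test_coverage = st_test_coverage,
              base_hit_rate = base_hit_rate,
              n_scaffold_families = as.integer(n_scaffold_families),
              analogs_per_family = as.integer(min(analogs_per_family,
                                                  family_capacity())),
              separate_mt_families = isTRUE(separate_mt_families),
              family_target_coherence = family_target_coherence,
              frac_liability = frac_liability,
              frac_antitarget_assays = frac_antitarget_assays,
              frac_high_hit_rate_assays = frac_high_hit_rate_assays,
              n_inconsistent_pairs = as.integer(n_inconsistent_pairs),
              seed = as.integer(seed))
  class(cfg) <- "world_config"
  cfg
}

# structures for a given per-compound family assignment; assumes an active
# RNG state (callers wrap in withr::with_seed)
gen_structures_for_families <- function(families) {
  templates <- scaffold_templates()
  subs <- substituent_library()
  cap <- family_capacity()
  counts <- table(families)
  if (any(counts > cap)) {
    stop("requested compounds exceed enumerable analogs per family (",
         cap, ")", call. = FALSE)
  }
  smiles <- character(length(families))
  for (f in as.integer(names(counts))) {
    members <- which(families == f)
    fixed <- sample(subs, 1)
    vary <- sample(subs, length(members))
    smiles[members] <- sprintf(templates[f], vary, fixed)
  }
  smiles
}

#' Generate compound structures
#'
#' Enumerates substituent patterns on per-family core scaffolds: compounds
#' are assigned round-robin to `n_scaffold_families` families and each
#' family's members receive distinct substituent pairs on the family core.
#' All emitted SMILES are valid and globally distinct; within-family
#' fingerprint similarity exceeds between-family similarity on average.
#'
#' @param config A [world_config()].
#' @return Named character vector, compound id -> SMILES.
#' @export
generate_structures <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cids <- sprintf("C%05d", seq_len(config$n_compounds))
  fams <- (seq_len(config$n_compounds) - 1L) %% config$n_scaffold_families + 1L
  if (any(table(fams) > config$analogs_per_family)) {
    stop("requested compounds exceed enumerable analogs (analogs_per_family)",
         call. = FALSE)
  }
  smiles <- withr::with_seed(config$seed, gen_structures_for_families(fams))
  stats::setNames(smiles, cids)
}

assign_families <- function(config, is_mt) {
  n_fam <- config$n_scaffold_families
  cap <- min(config$analogs_per_family, family_capacity())
  n <- length(is_mt)
  if (!config$separate_mt_families) {
    fam <- (seq_len(n) - 1L) %% n_fam + 1L
  } else {
    n_mt <- sum(is_mt)
    n_st <- n - n_mt
    n_mt_f <- round(n_fam * n_mt / n)
    n_mt_f <- max(n_mt_f, ceiling(n_mt / cap), if (n_mt > 0) 1L else 0L)
    n_mt_f <- min(n_mt_f, n_fam - ceiling(n_st / cap))
    if (n_mt > 0 && (n_mt_f < 1 || n_mt_f > n_fam - (n_st > 0))) {
      stop("infeasible family split for separate_mt_families", call. = FALSE)
    }
    fam <- integer(n)
    fam[is_mt] <- (seq_len(n_mt) - 1L) %% n_mt_f + 1L
    fam[!is_mt] <- n_mt_f + (seq_len(n_st) - 1L) %% (n_fam - n_mt_f) + 1L
  }
  if (any(table(fam) > cap)) {
    stop("requested compounds exceed enumerable analogs per family",
         call. = FALSE)
  }
  fam
}

#' Generate a complete synthetic screening world
#'
#' Emits assay metadata, compound structures and activity records together
#' with the planted ground truth. Each compound receives a planted
#' promiscuity degree from `pd_distribution` and a uniformly drawn
#' active-target set of that size; every active pair is emitted as an
#' active record, and every other (compound, target) pair is tested with
#' probability `test_coverage` (PD = 1 compounds: `st_test_coverage`) and
#' emitted as an inactive record. Violation knobs plant extra antitarget
#' assays, high-hit-rate assays (5 percent), active+inactive conflicts in
#' distinct assays of one target, and deny-listed liability compounds.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world`: `assays` (an
#'   [assay_table()]), `compounds` (a [compound_table()]), `records` (an
#'   [activity_records()] table) and `truth` (planted PD, outcome matrix,
#'   family ids, liability ids and rule sets, violation assay ids,
#'   inconsistent pairs, and the configuration).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (config$n_inconsistent_pairs > 0 && config$n_assays_per_target < 2) {
    stop("planting inconsistent pairs needs n_assays_per_target >= 2",
         call. = FALSE)
  }
  withr::with_seed(config$seed, {
    n <- config$n_compounds
    cids <- sprintf("C%05d", seq_len(n))
    targets <- sprintf("T%03d", seq_len(config$n_targets))
    pdv <- as.integer(names(config$pd_distribution))
    pd <- sample(pdv, n, replace = TRUE, prob = config$pd_distribution)
    is_mt <- pd >= 2L
    fam <- assign_families(config, is_mt)
    smiles <- gen_structures_for_families(fam)

    # planted ternary outcome table; with target coherence a compound
    # inherits its family's home targets (leading block of the family's
    # target permutation), emulating series-level structure-activity
    # coherence
    fam_perm <- lapply(seq_len(config$n_scaffold_families),
                       function(f) sample.int(config$n_targets))
    outcome <- matrix(OUTCOME_UNTESTED, n, config$n_targets,
                      dimnames = list(cids, targets))
    st_cov <- if (is.null(config$st_test_coverage)) config$test_coverage
              else config$st_test_coverage
    for (i in seq_len(n)) {
      act <- if (stats::runif(1) < config$family_target_coherence)
        fam_perm[[fam[i]]][seq_len(pd[i])]
      else sample.int(config$n_targets, pd[i])
      outcome[i, act] <- OUTCOME_ACTIVE
      rest <- setdiff(seq_len(config$n_targets), act)
      cov <- if (pd[i] == 1L) st_cov else config$test_coverage
      tested <- rest[stats::runif(length(rest)) < cov]
      outcome[i, tested] <- OUTCOME_INACTIVE
    }

    # one record per tested pair, in a random assay of the pair's target
    pairs <- which(outcome != OUTCOME_UNTESTED, arr.ind = TRUE)
    rec <- data.frame(
      compound_id = cids[pairs[, 1]],
      target_id = targets[pairs[, 2]],
      assay_no = sample.int(config$n_assays_per_target, nrow(pairs),
                            replace = TRUE),
      outcome = ifelse(outcome[pairs] == OUTCOME_ACTIVE, "active", "inactive"),
      stringsAsFactors = FALSE)
    rec$assay_id <- sprintf("%s_A%d", rec$target_id, rec$assay_no)

    # planted violations -------------------------------------------------
    n_main <- config$n_targets * config$n_assays_per_target
    n_anti <- round(config$frac_antitarget_assays * n_main)
    anti_targets <- if (n_anti > 0) sprintf("AT%02d", seq_len(n_anti))
                    else character(0)
    anti_assays <- sprintf("%s_A1", anti_targets)
    anti_rec <- NULL
    if (n_anti > 0) {
      anti_rec <- do.call(rbind, lapply(seq_len(n_anti), function(k) {
        who <- sample(cids, min(3L, n))
        data.frame(compound_id = who, target_id = anti_targets[k],
                   assay_no = 1L, outcome = "active",
                   assay_id = anti_assays[k], stringsAsFactors = FALSE)
      }))
    }

    n_hh <- round(config$frac_high_hit_rate_assays * n_main)
    hh_assays <- if (n_hh > 0) sprintf("HH%02d_A1", seq_len(n_hh))
                 else character(0)
    hh_targets <- if (n_hh > 0) sample(targets, n_hh, replace = TRUE)
                  else character(0)

    incon_pairs <- NULL
    incon_rec <- NULL
    if (config$n_inconsistent_pairs > 0) {
      cand <- which(!duplicated(rec[c("compound_id", "target_id")]))
      pick <- sample(cand, config$n_inconsistent_pairs)
      incon_pairs <- rec[pick, c("compound_id", "target_id"), drop = FALSE]
      flip <- ifelse(rec$outcome[pick] == "active", "inactive", "active")
      other_no <- rec$assay_no[pick] %% config$n_assays_per_target + 1L
      incon_rec <- data.frame(
        compound_id = rec$compound_id[pick], target_id = rec$target_id[pick],
        assay_no = other_no, outcome = flip,
        assay_id = sprintf("%s_A%d", rec$target_id[pick], other_no),
        stringsAsFactors = FALSE)
    }

    n_liab <- round(config$frac_liability * n)
    liab_cids <- if (n_liab > 0) sort(sample(cids, n_liab)) else character(0)
    half <- length(liab_cids) %/% 2L
    rule_sets <- list(
      liability_ruleset("aggregator",
                        deny_list = liab_cids[seq_len(half)]),
      liability_ruleset("fluc_inhibitor",
                        deny_list = liab_cids[setdiff(seq_along(liab_cids),
                                                      seq_len(half))]))

    all_rec <- rbind(rec, anti_rec, incon_rec)
    records <- activity_records(all_rec$compound_id, all_rec$target_id,
                                all_rec$assay_id, all_rec$outcome)

    # assay metadata; substance counts padded so non-violation assays stay
    # below the hit-rate cutoff, violation assays sit at 5%
    main_assays <- as.vector(t(outer(targets, seq_len(config$n_assays_per_target),
                                     function(t, k) sprintf("%s_A%d", t, k))))
    meta_ids <- c(main_assays, anti_assays, hh_assays)
    meta_targets <- c(rep(targets, each = config$n_assays_per_target),
                      anti_targets, hh_targets)
    n_rec <- table(factor(records$assay_id, levels = meta_ids))
    n_act <- table(factor(records$assay_id[records$outcome == "active"],
                          levels = meta_ids))
    n_tested_meta <- pmax(as.integer(n_rec),
                          ceiling(as.integer(n_act) / config$base_hit_rate),
                          50L)
    n_active_meta <- as.integer(n_act)
    hh_idx <- meta_ids %in% hh_assays
    n_tested_meta[hh_idx] <- 200L
    n_active_meta[hh_idx] <- 10L
    assays <- assay_table(
      assay_id = meta_ids, target_id = meta_targets,
      assay_format = "biochemical", source = "native",
      n_tested = n_tested_meta, n_active = n_active_meta,
      flags = ifelse(meta_ids %in% anti_assays, "antitarget", ""))

    incon_assays <- character(0)
    if (!is.null(incon_pairs)) {
      key <- paste(records$compound_id, records$target_id)
      bad_key <- paste(incon_pairs$compound_id, incon_pairs$target_id)
      incon_assays <- sort(unique(records$assay_id[key %in% bad_key]))
    }

    truth <- list(pd = stats::setNames(pd, cids),
                  outcome = outcome,
                  family = stats::setNames(fam, cids),
                  liability = liab_cids,
                  rule_sets = rule_sets,
                  antitarget_ids = anti_targets,
                  antitarget_assays = anti_assays,
                  high_hit_rate_assays = hh_assays,
                  inconsistent_assays = incon_assays,
                  inconsistent_pairs = incon_pairs,
                  config = config)
    structure(list(assays = assays,
                   compounds = compound_table(cids, smiles),
                   records = records,
                   truth = truth),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d compounds, %d targets, %d assays, %d records>\n",
              nrow(x$compounds), x$truth$config$n_targets, nrow(x$assays),
              nrow(x$records)))
  invisible(x)
}

#' Preset world configurations
#'
#' Named worlds used throughout the test suite and documentation:
#' `tiny` (40 compounds, loads instantly), `conflict` (3 planted
#' inconsistent pairs), `liability` (20 percent planted interference
#' compounds), `attrition` (all violation knobs on), `contrast` (higher ST
#' test coverage, the test-frequency contrast), `analog` (many small
#' class-pure analog families; nearest-neighbor structure between groups)
#' and `separable` (large analog world with structurally separated MT/ST
#' classes for the prediction benchmark).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `world_config`.
#' @export
world_preset <- function(name = c("tiny", "conflict", "liability",
                                  "attrition", "contrast", "analog",
                                  "separable"),
                         seed = 1L) {
  name <- match.arg(name)
  tiny <- list(n_targets = 6L, n_assays_per_target = 1L, n_compounds = 40L,
               pd_distribution = c("1" = 0.7, "5" = 0.3),
               test_coverage = 0.9, n_scaffold_families = 4L,
               analogs_per_family = 12L, seed = seed)
  args <- switch(name,
    tiny = tiny,
    conflict = utils::modifyList(tiny, list(n_assays_per_target = 2L,
                                            n_inconsistent_pairs = 3L)),
    liability = utils::modifyList(tiny, list(frac_liability = 0.2)),
    attrition = list(n_targets = 8L, n_assays_per_target = 2L,
                     n_compounds = 60L,
                     pd_distribution = c("1" = 0.7, "5" = 0.3),
                     test_coverage = 0.9, n_scaffold_families = 6L,
                     analogs_per_family = 12L,
                     frac_antitarget_assays = 0.25,
                     frac_high_hit_rate_assays = 0.25,
                     n_inconsistent_pairs = 2L, frac_liability = 0.1,
                     seed = seed),
    contrast = list(n_targets = 12L, n_assays_per_target = 1L,
                    n_compounds = 60L,
                    pd_distribution = c("1" = 0.7, "5" = 0.3),
                    test_coverage = 0.5, st_test_coverage = 0.95,
                    n_scaffold_families = 6L, analogs_per_family = 12L,
                    seed = seed),
    analog = list(n_targets = 10L, n_assays_per_target = 1L,
                  n_compounds = 220L,
                  pd_distribution = c("1" = 0.82, "5" = 0.12, "6" = 0.06),
                  test_coverage = 0.9, n_scaffold_families = 40L,
                  analogs_per_family = 12L, separate_mt_families = TRUE,
                  family_target_coherence = 0.9, seed = seed),
    separable = list(n_targets = 8L, n_assays_per_target = 1L,
                     n_compounds = 1200L,
                     pd_distribution = c("1" = 0.8, "5" = 0.13, "6" = 0.07),
                     test_coverage = 0.85, n_scaffold_families = 60L,
                     analogs_per_family = 21L, separate_mt_families = TRUE,
                     family_target_coherence = 0.9, seed = seed))
  do.call(world_config, args)
}

write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(world$assays, file.path(dir, "assays.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$compounds, file.path(dir, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$records[c("compound_id", "target_id", "assay_id",
                                     "outcome")],
                     file.path(dir, "records.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- world$truth
  tr <- list(
    pd = as.list(truth$pd),
    family = as.list(truth$family),
    liability = truth$liability,
    antitarget_ids = truth$antitarget_ids,
    antitarget_assays = truth$antitarget_assays,
    high_hit_rate_assays = truth$high_hit_rate_assays,
    inconsistent_assays = truth$inconsistent_assays,
    outcome = list(compounds = rownames(truth$outcome),
                   targets = colnames(truth$outcome),
                   codes = unname(apply(truth$outcome, 1, as.list,
                                        simplify = FALSE))))
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write the named fixture-world suite
#'
#' Materializes the preset worlds (`tiny`, `conflict`, `liability`,
#' `analog`, `separable`) as tab-delimited tables plus a `truth.json`
#' ground-truth file under one directory per world.
#'
#' @param out_dir Writable output directory.
#' @param seed Seed forwarded to every preset.
#' @return `out_dir`, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  for (name in c("tiny", "conflict", "liability", "analog", "separable")) {
    write_world(generate_world(world_preset(name, seed)),
                file.path(out_dir, name))
  }
  invisible(out_dir)
}
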