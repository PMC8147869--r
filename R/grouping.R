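# Ternary activity matrix, promiscuity degrees, test frequencies, MT
# selection and the central group-assembly algorithm: one MT compound per
# group plus at most one experimentally confirmed ST compound per group
# target, with a global ST-uniqueness constraint and a completeness
# certificate (no member untested on any group target).

OUTCOME_UNTESTED <- 0L
OUTCOME_INACTIVE <- 1L
OUTCOME_ACTIVE <- 2L

#' Build the ternary compound x target activity matrix
#'
#' Collapses assay-level records to compound-target calls: a pair is active
#' when any retained record reports it active, inactive when all its
#' records are inactive, untested when no record exists. Conflicting pairs
#' (both outcomes present) indicate that inconsistency curation was
#' skipped and raise an error naming the pair.
#'
#' @param records An `activity_records` table with conflicts already
#'   resolved (see [resolve_inconsistencies()]).
#' @return An object of class `activity_matrix`: integer matrix coded
#'   0 = untested, 1 = inactive, 2 = active, with compound rownames and
#'   target colnames in first-appearance order.
#' @export
build_activity_matrix <- function(records) {
  dt <- data.table::as.data.table(records)
  compounds <- unique(dt$compound_id)
  targets <- unique(dt$target_id)
  m <- matrix(OUTCOME_UNTESTED, nrow = length(compounds), ncol = length(targets),
              dimnames = list(compounds, targets))
  if (nrow(dt)) {
    calls <- dt[, .(n_out = length(unique(outcome)), outcome = outcome[1]),
                by = .(compound_id, target_id)]
    if (any(calls$n_out > 1)) {
      bad <- calls[n_out > 1][1]
      stop("conflicting outcomes for pair (", bad$compound_id, ", ",
           bad$target_id, "); run inconsistency curation first", call. = FALSE)
    }
    idx <- cbind(match(calls$compound_id, compounds),
                 match(calls$target_id, targets))
    m[idx] <- ifelse(calls$outcome == "active", OUTCOME_ACTIVE, OUTCOME_INACTIVE)
  }
  structure(list(outcome = m, compounds = compounds, targets = targets),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix: %d compounds x %d targets, %d active / %d inactive calls>\n",
              length(x$compounds), length(x$targets),
              sum(x$outcome == OUTCOME_ACTIVE), sum(x$outcome == OUTCOME_INACTIVE)))
  invisible(x)
}

matrix_row <- function(matrix, compound) {
  if (!(compound %in% matrix$compounds)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  matrix$outcome[compound, ]
}

#' Promiscuity degree
#'
#' Number of targets a compound is active against in the curated activity
#' matrix. PD = 1 defines the single-target class; PD at or above the
#' dataset threshold defines the multi-target class.
#'
#' @param matrix An `activity_matrix`.
#' @param compound A compound id present in the matrix.
#' @return Integer count of active targets.
#' @export
promiscuity_degree <- function(matrix, compound) {
  sum(matrix_row(matrix, compound) == OUTCOME_ACTIVE)
}

#' Test frequency
#'
#' Number of targets a compound has any recorded outcome for (active or
#' inactive); the value deposited in the `n_tested` column. Always at
#' least the promiscuity degree.
#'
#' @inheritParams promiscuity_degree
#' @return Integer count of tested targets.
#' @export
test_frequency <- function(matrix, compound) {
  sum(matrix_row(matrix, compound) != OUTCOME_UNTESTED)
}

#' Per-compound promiscuity profiles
#'
#' Vectorized promiscuity degree and test frequency for every compound in
#' the matrix.
#'
#' @param matrix An `activity_matrix`.
#' @return A data.frame with columns `compound_id`, `pd`, `n_tested`.
#' @export
promiscuity_profile <- function(matrix) {
  data.frame(compound_id = matrix$compounds,
             pd = as.integer(rowSums(matrix$outcome == OUTCOME_ACTIVE)),
             n_tested = as.integer(rowSums(matrix$outcome != OUTCOME_UNTESTED)),
             stringsAsFactors = FALSE)
}

#' Select multi-target compounds
#'
#' Compounds with promiscuity degree at or above the threshold, ordered by
#' descending PD, then ascending compound id. The threshold is at least 2
#' (PD >= 5 is the significant-promiscuity criterion, PD >= 3 the control).
#'
#' @param matrix An `activity_matrix`.
#' @param pd_min Integer threshold, >= 2.
#' @return Character vector of compound ids.
#' @export
select_mt <- function(matrix, pd_min = 5L) {
  if (pd_min < 2) stop("pd_min must be >= 2", call. = FALSE)
  prof <- promiscuity_profile(matrix)
  sel <- prof[prof$pd >= pd_min, , drop = FALSE]
  sel$compound_id[order(-sel$pd, sel$compound_id)]
}

#' Assemble experimentally complete MT/ST compound groups
#'
#' The central dataset-construction algorithm. MT compounds (PD >=
#' `pd_min`) are processed in [select_mt()] order. For each target of an MT
#' compound's active-target set, an ST compound (PD = 1) is sought that is
#' active against that target and experimentally confirmed inactive
#' against every remaining target of the set; each ST compound may be
#' selected for at most one group. Targets without a qualifying unused
#' candidate get no ST member; MT compounds ending up with zero ST members
#' are omitted. Every emitted group is complete: each member has a
#' recorded outcome for every group target.
#'
#' Tie-breaking among qualifying candidates (highest test frequency, then
#' lowest compound id) and the MT processing order (PD descending, then
#' compound id) make the output deterministic.
#'
#' @param matrix An `activity_matrix`.
#' @param pd_min MT threshold, integer >= 2.
#' @param name,assay_set Provenance recorded in the dataset.
#' @param smiles Optional named SMILES vector stored for writing.
#' @return A `promiscuity_dataset` with groups numbered `0..n-1` in
#'   assembly order.
#' @export
assemble_groups <- function(matrix, pd_min = 5L, name = "dataset",
                            assay_set = "biochemical", smiles = NULL) {
  if (pd_min < 2) stop("pd_min must be >= 2", call. = FALSE)
  prof <- promiscuity_profile(matrix)
  mt_ids <- select_mt(matrix, pd_min)
  st_pool <- prof[prof$pd == 1L, , drop = FALSE]
  # candidate order: most evidence first, then stable id order
  st_pool <- st_pool[order(-st_pool$n_tested, st_pool$compound_id), , drop = FALSE]
  used <- character(0)
  active <- matrix$outcome == OUTCOME_ACTIVE
  untested <- matrix$outcome == OUTCOME_UNTESTED
  groups <- list()
  for (mt in mt_ids) {
    tset <- matrix$targets[active[mt, ]]
    st_members <- character(0)
    for (t in tset) {
      others <- setdiff(tset, t)
      for (cand in setdiff(st_pool$compound_id, used)) {
        if (!active[cand, t]) next
        # confirmed inactive on every remaining group target
        if (length(others) && any(matrix$outcome[cand, others] != OUTCOME_INACTIVE))
          next
        st_members[t] <- cand
        used <- c(used, cand)
        break
      }
    }
    if (length(st_members) == 0) next
    members <- c(mt, unname(st_members))
    n_tested <- stats::setNames(
      as.integer(rowSums(!untested[members, , drop = FALSE])), members)
    groups[[length(groups) + 1L]] <- compound_group(
      group_id = length(groups), mt_compound = mt, target_set = tset,
      st_members = st_members, n_tested = n_tested)
  }
  smi <- NULL
  if (!is.null(smiles)) {
    cids <- unlist(lapply(groups, group_members), use.names = FALSE)
    smi <- smiles[cids]
  }
  promiscuity_dataset(groups, name = name, assay_set = assay_set,
                      pd_threshold = pd_min, smiles = smi)
}

#' Verify group completeness and class membership
#'
#' Confirms, against the activity matrix, that every group member has a
#' recorded outcome for every group target, that the MT member's
#' promiscuity degree reaches the dataset threshold, that every ST member
#' has PD exactly 1 and is active on its assigned target, and that no ST
#' compound appears in two groups.
#'
#' @param dataset A `promiscuity_dataset`.
#' @param matrix The `activity_matrix` it was assembled from.
#' @return A list of class `completeness_report` with `n_violations` and a
#'   data.frame `violations` (columns `group_id`, `compound_id`,
#'   `target_id`, `rule`).
#' @export
verify_completeness <- function(dataset, matrix) {
  v <- list()
  note <- function(gid, cid, tid, rule) {
    v[[length(v) + 1L]] <<- data.frame(group_id = gid, compound_id = cid,
                                       target_id = tid, rule = rule,
                                       stringsAsFactors = FALSE)
  }
  prof <- promiscuity_profile(matrix)
  pd <- stats::setNames(prof$pd, prof$compound_id)
  seen_st <- character(0)
  for (g in dataset$groups) {
    for (cid in group_members(g)) {
      if (!(cid %in% matrix$compounds)) {
        note(g$group_id, cid, NA_character_, "unknown_compound")
        next
      }
      miss <- g$target_set[matrix$outcome[cid, g$target_set] == OUTCOME_UNTESTED]
      for (t in miss) note(g$group_id, cid, t, "incomplete")
    }
    if (g$mt_compound %in% matrix$compounds &&
        pd[g$mt_compound] < dataset$pd_threshold) {
      note(g$group_id, g$mt_compound, NA_character_, "mt_pd_below_threshold")
    }
    for (t in names(g$st_members)) {
      cid <- g$st_members[[t]]
      if (!(cid %in% matrix$compounds)) next
      if (pd[cid] != 1L) note(g$group_id, cid, NA_character_, "st_pd_not_one")
      if (matrix$outcome[cid, t] != OUTCOME_ACTIVE) {
        note(g$group_id, cid, t, "st_not_active_on_target")
      }
      if (cid %in% seen_st) note(g$group_id, cid, NA_character_, "st_reused")
      seen_st <- c(seen_st, cid)
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(group_id = integer(0), compound_id = character(0),
               target_id = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  structure(list(n_violations = nrow(violations), violations = violations),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  if (x$n_violations == 0) cat("completeness: OK (0 violations)\n")
  else {
    cat("completeness: ", x$n_violations, " violation(s)\n", sep = "")
    print(utils::head(x$violations, 20))
  }
  invisible(x)
}
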