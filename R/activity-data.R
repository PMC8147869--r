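# Core data model: screening records, MT/ST compound groups, promiscuity
# datasets, and the deposited tab-delimited dialect (reader, writer,
# summaries, deposition verification).

DATASET_COLUMNS <- c("NostereoAromaticSMILES", "is_MT", "group", "cid",
                     "target_ids", "n_tested", "random_removal_set",
                     "nn_removal_set")

ASSAY_FLAGS <- c("inconsistent", "cytotoxic_readout", "antitarget",
                 "nonhuman", "unmapped_target")
LIABILITY_FLAGS <- c("pains", "chemical_liability", "aggregator",
                     "fluc_inhibitor", "cytotoxic")

#' Assay metadata table
#'
#' Builds and validates the assay-level metadata consumed by the curation
#' cascade. One row per assay.
#'
#' @param assay_id Unique assay identifiers.
#' @param target_id Protein identifiers (UniProt-style accessions).
#' @param assay_format `"biochemical"` or `"cell_based"`.
#' @param source `"native"` (assays originating in the screening database)
#'   or `"external"` (deposited from other databases, e.g. ChEMBL or Tox21).
#' @param n_tested,n_active Substance counts per assay; `n_active <= n_tested`.
#' @param flags `|`-separated curation flags per assay, out of
#'   `inconsistent`, `cytotoxic_readout`, `antitarget`, `nonhuman`,
#'   `unmapped_target`; `""` for none.
#' @return A `data.frame` of class `assay_table`.
#' @export
assay_table <- function(assay_id, target_id, assay_format = "biochemical",
                        source = "native", n_tested = 0L, n_active = 0L,
                        flags = "") {
  df <- data.frame(assay_id = as.character(assay_id),
                   target_id = as.character(target_id),
                   assay_format = as.character(assay_format),
                   source = as.character(source),
                   n_tested = as.integer(n_tested),
                   n_active = as.integer(n_active),
                   flags = as.character(flags),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$assay_id)) stop("duplicate assay_id", call. = FALSE)
  stopifnot(all(df$assay_format %in% c("biochemical", "cell_based")),
            all(df$source %in% c("native", "external")),
            all(df$n_active <= df$n_tested), all(df$n_active >= 0))
  bad <- setdiff(unlist(strsplit(df$flags[nzchar(df$flags)], "|", fixed = TRUE)),
                 ASSAY_FLAGS)
  if (length(bad)) stop("unknown assay flag: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(df) <- c("assay_table", "data.frame")
  df
}

#' Activity outcome records
#'
#' One row per reported compound-target-assay outcome. Outcomes are binary
#' active/inactive calls; no potency values are stored.
#'
#' @param compound_id,target_id,assay_id Identifier vectors (recycled to a
#'   common length).
#' @param outcome `"active"` or `"inactive"`.
#' @return A `data.frame` of class `activity_records`.
#' @export
activity_records <- function(compound_id, target_id, assay_id, outcome) {
  df <- data.frame(compound_id = as.character(compound_id),
                   target_id = as.character(target_id),
                   assay_id = as.character(assay_id),
                   outcome = as.character(outcome),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$outcome %in% c("active", "inactive")))
  class(df) <- c("activity_records", "data.frame")
  df
}

#' Compound record table
#'
#' @param compound_id Unique compound identifiers (cids).
#' @param smiles Canonical no-stereo aromatic SMILES.
#' @param liability_flags `|`-separated flags out of `pains`,
#'   `chemical_liability`, `aggregator`, `fluc_inhibitor`, `cytotoxic`.
#' @return A `data.frame` of class `compound_table`.
#' @export
compound_table <- function(compound_id, smiles, liability_flags = "") {
  df <- data.frame(compound_id = as.character(compound_id),
                   smiles = as.character(smiles),
                   liability_flags = as.character(liability_flags),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$compound_id)) stop("duplicate compound_id", call. = FALSE)
  class(df) <- c("compound_table", "data.frame")
  df
}

#' One MT/ST compound group
#'
#' A group is one multi-target (MT) compound, the ordered set of targets it
#' is active against, and at most one single-target (ST) compound per
#' target. Groups with zero ST members are never emitted by the assembly
#' algorithm and are rejected here.
#'
#' @param group_id Integer group identifier.
#' @param mt_compound Compound id of the MT member.
#' @param target_set Character vector of target ids (order is meaningful).
#' @param st_members Named character vector mapping target id -> ST
#'   compound id; names must be a subset of `target_set`.
#' @param n_tested Named integer vector: test frequency of every member
#'   (MT and ST compounds).
#' @return An object of class `compound_group`.
#' @export
compound_group <- function(group_id, mt_compound, target_set, st_members,
                           n_tested) {
  st_members <- st_members[order(match(names(st_members), target_set))]
  g <- structure(list(group_id = as.integer(group_id),
                      mt_compound = as.character(mt_compound),
                      target_set = as.character(target_set),
                      st_members = st_members,
                      n_tested = n_tested),
                 class = "compound_group")
  validate_group(g)
  g
}

validate_group <- function(g) {
  if (length(g$st_members) < 1) {
    stop("group ", g$group_id, ": zero ST members", call. = FALSE)
  }
  if (!all(names(g$st_members) %in% g$target_set)) {
    stop("group ", g$group_id, ": ST member target outside target set",
         call. = FALSE)
  }
  if (g$mt_compound %in% g$st_members) {
    stop("group ", g$group_id, ": MT compound reused as ST member",
         call. = FALSE)
  }
  if (anyDuplicated(names(g$st_members)) || anyDuplicated(g$st_members)) {
    stop("group ", g$group_id, ": duplicated ST target or compound",
         call. = FALSE)
  }
  members <- c(g$mt_compound, unname(g$st_members))
  if (!all(members %in% names(g$n_tested))) {
    stop("group ", g$group_id, ": missing n_tested for a member", call. = FALSE)
  }
  invisible(g)
}

group_members <- function(g) c(g$mt_compound, unname(g$st_members))

#' A named collection of MT/ST compound groups
#'
#' The central container: groups plus provenance (assay-set kind, the
#' promiscuity-degree threshold that defined MT membership), per-compound
#' SMILES, and removal marks identifying the randomly removed and the
#' nearest-neighbor-removed halves.
#'
#' @param groups List of [compound_group()] objects with distinct ids; every
#'   compound may appear in exactly one group.
#' @param name Dataset name.
#' @param assay_set `"mixed"` or `"biochemical"`.
#' @param pd_threshold Integer >= 2; minimum promiscuity degree of the MT class.
#' @param smiles Named character vector mapping compound id -> SMILES
#'   (may be `NULL` when structures are not needed).
#' @param removal_marks List with character-vector elements
#'   `random_removal_set` and `nn_removal_set` of compound ids.
#' @return An object of class `promiscuity_dataset`.
#' @export
promiscuity_dataset <- function(groups, name = "dataset",
                                assay_set = c("mixed", "biochemical"),
                                pd_threshold = 5L, smiles = NULL,
                                removal_marks = list(
                                  random_removal_set = character(0),
                                  nn_removal_set = character(0))) {
  assay_set <- match.arg(assay_set)
  stopifnot(pd_threshold >= 2)
  ds <- structure(list(name = name, assay_set = assay_set,
                       pd_threshold = as.integer(pd_threshold),
                       groups = groups, smiles = smiles,
                       removal_marks = removal_marks),
                  class = "promiscuity_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a promiscuity dataset
#'
#' Checks the container invariants: distinct group ids, every compound in
#' exactly one group, per-group structural validity.
#'
#' @param dataset A `promiscuity_dataset`.
#' @return The dataset, invisibly; errors on violation.
#' @export
validate_dataset <- function(dataset) {
  ids <- vapply(dataset$groups, `[[`, integer(1), "group_id")
  if (anyDuplicated(ids)) stop("duplicate group ids", call. = FALSE)
  for (g in dataset$groups) validate_group(g)
  members <- unlist(lapply(dataset$groups, group_members), use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("compound in more than one group: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(dataset)
}

dataset_compounds <- function(dataset) {
  unlist(lapply(dataset$groups, group_members), use.names = FALSE)
}

#' @export
print.promiscuity_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf("<promiscuity_dataset '%s': %s assays, PD>=%d, %d groups, %d MT + %d ST compounds, %d targets>\n",
              x$name, x$assay_set, x$pd_threshold, s$n_groups, s$n_mt, s$n_st,
              s$n_targets))
  invisible(x)
}

#' Summarize dataset composition
#'
#' Counts MT and ST compounds, groups and distinct targets, and tabulates
#' the number of ST members per MT compound (the group-size histogram).
#'
#' @param dataset A `promiscuity_dataset`.
#' @return A list of class `dataset_summary` with elements `n_mt`, `n_st`,
#'   `n_groups`, `n_targets` and `st_per_mt_histogram` (named integer
#'   vector keyed by ST-per-MT count).
#' @export
dataset_summary <- function(dataset) {
  validate_dataset(dataset)
  sizes <- vapply(dataset$groups, function(g) length(g$st_members), integer(1))
  targets <- unique(unlist(lapply(dataset$groups, `[[`, "target_set")))
  hist <- if (length(sizes)) table(sizes) else table(integer(0))
  hist <- stats::setNames(as.integer(hist), names(hist))
  structure(list(n_mt = length(dataset$groups),
                 n_st = sum(sizes),
                 n_groups = length(dataset$groups),
                 n_targets = length(targets),
                 st_per_mt_histogram = hist),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("MT compounds: %d\nST compounds: %d\nGroups: %d\nTargets: %d\n",
              x$n_mt, x$n_st, x$n_groups, x$n_targets))
  if (length(x$st_per_mt_histogram)) {
    cat("ST per MT:",
        paste(sprintf("%s:%d", names(x$st_per_mt_histogram),
                      x$st_per_mt_histogram), collapse = " "), "\n")
  }
  invisible(x)
}

parse_bool_column <- function(x, column) {
  out <- rep(NA, length(x))
  out[x %in% c("True", "true", "TRUE", "1")] <- TRUE
  out[x %in% c("False", "false", "FALSE", "0")] <- FALSE
  if (anyNA(out) && length(x)) {
    stop("column '", column, "': unrecognized boolean value '",
         x[which(is.na(out))[1]], "'", call. = FALSE)
  }
  out
}

detect_list_separator <- function(values) {
  for (sep in c(";", ",", "|")) {
    if (any(grepl(sep, values, fixed = TRUE))) return(sep)
  }
  ";"
}

#' Read a dataset from the deposited tab-delimited dialect
#'
#' Parses a tab-delimited file with the seven deposited columns
#' (`NostereoAromaticSMILES`, `is_MT`, `group`, `cid`, `target_ids`,
#' `n_tested`, `random_removal_set`, `nn_removal_set`), one row per
#' compound. The MT row of each group carries the full target list; each ST
#' row carries its assigned target. The list separator is auto-detected
#' among `;`, `,` and `|`; booleans are read liberally
#' (`True/False/true/false/1/0`).
#'
#' @param path Path to a `.tsv` file.
#' @param name,assay_set,pd_threshold Provenance metadata for the returned
#'   dataset (not stored in the file).
#' @return A `promiscuity_dataset`. Round-trips with [write_dataset_tsv()]
#'   up to column order.
#' @export
read_dataset_tsv <- function(path, name = basename(path),
                             assay_set = "biochemical", pd_threshold = 5L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "")
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(promiscuity_dataset(list(), name = name, assay_set = assay_set,
                               pd_threshold = pd_threshold,
                               smiles = stats::setNames(character(0), character(0))))
  }
  if (anyDuplicated(df$cid)) {
    stop("duplicate cid: ", df$cid[which(duplicated(df$cid))[1]], call. = FALSE)
  }
  df$is_MT <- parse_bool_column(df$is_MT, "is_MT")
  df$.random <- parse_bool_column(df$random_removal_set, "random_removal_set")
  df$.nn <- parse_bool_column(df$nn_removal_set, "nn_removal_set")
  sep <- detect_list_separator(df$target_ids[df$is_MT])
  df$n_tested <- as.integer(df$n_tested)

  groups <- list()
  for (gid in unique(df$group)) {
    rows <- df[df$group == gid, , drop = FALSE]
    mt <- rows[rows$is_MT, , drop = FALSE]
    if (nrow(mt) != 1) {
      stop("group ", gid, ": expected exactly 1 MT row, found ", nrow(mt),
           call. = FALSE)
    }
    target_set <- strsplit(mt$target_ids, sep, fixed = TRUE)[[1]]
    st <- rows[!rows$is_MT, , drop = FALSE]
    st_targets <- st$target_ids
    if (any(grepl(sep, st_targets, fixed = TRUE))) {
      stop("group ", gid, ": ST row carries a target list", call. = FALSE)
    }
    if (!all(st_targets %in% target_set)) {
      stop("group ", gid, ": rows disagree on target_ids (ST target not in ",
           "the group's target set)", call. = FALSE)
    }
    if (anyDuplicated(st_targets)) {
      stop("group ", gid, ": two ST rows claim one target", call. = FALSE)
    }
    n_tested <- stats::setNames(rows$n_tested, rows$cid)
    groups[[length(groups) + 1L]] <- compound_group(
      group_id = as.integer(gid), mt_compound = mt$cid,
      target_set = target_set,
      st_members = stats::setNames(st$cid, st_targets),
      n_tested = n_tested)
  }
  promiscuity_dataset(
    groups, name = name, assay_set = assay_set, pd_threshold = pd_threshold,
    smiles = stats::setNames(df$NostereoAromaticSMILES, df$cid),
    removal_marks = list(random_removal_set = df$cid[df$.random],
                         nn_removal_set = df$cid[df$.nn]))
}

#' Write a dataset in the deposited tab-delimited dialect
#'
#' Emits exactly the seven deposited columns, tab-delimited with a header
#' row, one row per compound. Row order is deterministic: groups by
#' ascending id (renumbered `0..n-1`), the MT row first, then ST rows in
#' target-set order. Booleans are written as `True`/`False`; target lists
#' joined with `;`.
#'
#' @param dataset A valid `promiscuity_dataset` with SMILES for every
#'   compound.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, path) {
  validate_dataset(dataset)
  ord <- order(vapply(dataset$groups, `[[`, integer(1), "group_id"))
  rows <- list()
  for (k in seq_along(ord)) {
    g <- dataset$groups[[ord[k]]]
    cids <- group_members(g)
    smi <- dataset$smiles[cids]
    if (is.null(dataset$smiles) || anyNA(smi)) {
      stop("missing SMILES for group ", g$group_id, call. = FALSE)
    }
    rows[[k]] <- data.frame(
      NostereoAromaticSMILES = unname(smi),
      is_MT = c("True", rep("False", length(g$st_members))),
      group = k - 1L,
      cid = cids,
      target_ids = c(paste(g$target_set, collapse = ";"), names(g$st_members)),
      n_tested = unname(g$n_tested[cids]),
      random_removal_set = ifelse(
        cids %in% dataset$removal_marks$random_removal_set, "True", "False"),
      nn_removal_set = ifelse(
        cids %in% dataset$removal_marks$nn_removal_set, "True", "False"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(character(0), ncol = 8)), DATASET_COLUMNS)
  names(out) <- DATASET_COLUMNS
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Verify a deposited dataset collection
#'
#' Structural and composition checks for the three deposited dataset files:
#' unique cids, consistent per-group target lists (enforced by the reader),
#' and the published composition counts for the mixed PD>=5 (2858 MT /
#' 15839 ST), biochemical PD>=5 (1242 / 6629) and biochemical PD>=3
#' (3468 / 11793) datasets.
#'
#' @param mixed_pd5,biochemical_pd5,biochemical_pd3 Paths to the three
#'   deposited `.tsv` files.
#' @return A data.frame with one row per file: observed and expected MT/ST
#'   counts and a logical `ok` column.
#' @export
verify_deposition <- function(mixed_pd5, biochemical_pd5, biochemical_pd3) {
  spec <- data.frame(
    file = c(mixed_pd5, biochemical_pd5, biochemical_pd3),
    assay_set = c("mixed", "biochemical", "biochemical"),
    pd_threshold = c(5L, 5L, 3L),
    expect_mt = c(2858L, 1242L, 3468L),
    expect_st = c(15839L, 6629L, 11793L),
    stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(spec)), function(i) {
    ds <- read_dataset_tsv(spec$file[i], assay_set = spec$assay_set[i],
                           pd_threshold = spec$pd_threshold[i])
    s <- dataset_summary(ds)
    data.frame(n_mt = s$n_mt, n_st = s$n_st)
  })
  res <- do.call(rbind, res)
  out <- cbind(spec, res)
  out$ok <- out$n_mt == out$expect_mt & out$n_st == out$expect_st
  out
}
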