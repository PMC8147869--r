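# Assay-level curation cascade: source restriction, target mapping,
# human-target and antitarget exclusion, hit-rate cutoff, inconsistency and
# cytotoxicity flags, assay-format restriction. Produces a per-rule
# attrition report mirroring the curation workflow figure.

#' Curation configuration
#'
#' @param max_hit_rate Assays with `n_active / n_tested` above this fraction
#'   are removed as unusually high hit-rate assays (default 0.02, i.e. the
#'   2 percent screening cutoff).
#' @param antitarget_ids Target ids excluded as antitargets (hERG, CYP
#'   isoforms, P-glycoprotein and the like).
#' @param allowed_sources Assay sources retained; default `"native"` drops
#'   assays deposited from external databases.
#' @param require_target_mapping Drop assays flagged `unmapped_target`.
#' @param require_human Drop assays flagged `nonhuman`.
#' @param assay_formats Formats retained; `c("biochemical","cell_based")`
#'   yields the mixed set, `"biochemical"` the biochemical subset.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(max_hit_rate = 0.02,
                            antitarget_ids = character(0),
                            allowed_sources = "native",
                            require_target_mapping = TRUE,
                            require_human = TRUE,
                            assay_formats = c("biochemical", "cell_based")) {
  stopifnot(max_hit_rate > 0, max_hit_rate <= 1,
            all(allowed_sources %in% c("native", "external")),
            all(assay_formats %in% c("biochemical", "cell_based")))
  structure(list(max_hit_rate = max_hit_rate,
                 antitarget_ids = as.character(antitarget_ids),
                 allowed_sources = allowed_sources,
                 require_target_mapping = isTRUE(require_target_mapping),
                 require_human = isTRUE(require_human),
                 assay_formats = assay_formats),
            class = "curation_config")
}

#' Assay hit rate
#'
#' Fraction of tested substances reported active, `n_active / n_tested`.
#'
#' @param assays An `assay_table` (or any data.frame with `n_active` and
#'   `n_tested` columns); all `n_tested` must be positive.
#' @return Numeric vector of hit rates in `[0, 1]`.
#' @export
compute_hit_rate <- function(assays) {
  if (any(assays$n_tested == 0)) {
    stop("hit rate undefined for assay with n_tested = 0: ",
         paste(assays$assay_id[assays$n_tested == 0], collapse = ", "),
         call. = FALSE)
  }
  assays$n_active / assays$n_tested
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, "|", fixed = TRUE), function(f) flag %in% f,
         logical(1))
}

#' Apply the assay curation cascade
#'
#' Rules are applied in a fixed order; each assay is removed by the first
#' rule it violates, so the attrition report attributes every removal to
#' exactly one rule. Order: source, target mapping, human target,
#' antitarget, hit rate, inconsistency flag, cytotoxic readout, assay
#' format.
#'
#' @param assays An `assay_table`.
#' @param config A [curation_config()].
#' @return A list with `retained` (character vector of assay ids, input
#'   order) and `report` (class `curation_report`: data.frame with columns
#'   `rule`, `removed`, `remaining`).
#' @export
filter_assays <- function(assays, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  if (anyDuplicated(assays$assay_id)) stop("duplicate assay_id", call. = FALSE)
  rules <- list(
    source = function(a) !(a$source %in% config$allowed_sources),
    target_mapping = function(a) {
      if (!config$require_target_mapping) rep(FALSE, nrow(a))
      else has_flag(a$flags, "unmapped_target")
    },
    nonhuman = function(a) {
      if (!config$require_human) rep(FALSE, nrow(a))
      else has_flag(a$flags, "nonhuman")
    },
    antitarget = function(a) a$target_id %in% config$antitarget_ids |
      has_flag(a$flags, "antitarget"),
    hit_rate = function(a) compute_hit_rate(a) > config$max_hit_rate,
    inconsistent = function(a) has_flag(a$flags, "inconsistent"),
    cytotoxic = function(a) has_flag(a$flags, "cytotoxic_readout"),
    assay_format = function(a) !(a$assay_format %in% config$assay_formats)
  )
  keep <- assays
  report <- data.frame(rule = names(rules), removed = 0L, remaining = 0L,
                       stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    drop <- if (nrow(keep)) rules[[i]](keep) else logical(0)
    keep <- keep[!drop, , drop = FALSE]
    report$removed[i] <- sum(drop)
    report$remaining[i] <- nrow(keep)
  }
  class(report) <- c("curation_report", "data.frame")
  list(retained = keep$assay_id, report = report)
}

#' Detect assays with inconsistent compound-target annotations
#'
#' A (compound, target) pair is inconsistent when it carries both an active
#' and an inactive outcome across the retained assays. Every assay
#' contributing any record to such a pair is returned.
#'
#' @param records An `activity_records` table.
#' @param retained Assay ids to consider (default: all in `records`).
#' @return Sorted character vector of inconsistent assay ids (possibly
#'   empty).
#' @export
detect_inconsistent_assays <- function(records,
                                       retained = unique(records$assay_id)) {
  dt <- data.table::as.data.table(records)[assay_id %in% retained]
  if (nrow(dt) == 0) return(character(0))
  conf <- dt[, .(conflict = length(unique(outcome)) > 1),
             by = .(compound_id, target_id)][conflict == TRUE]
  if (nrow(conf) == 0) return(character(0))
  bad <- dt[conf, on = c("compound_id", "target_id")]
  sort(unique(bad$assay_id))
}

#' Resolve inconsistent annotations
#'
#' Removes the conflict either at assay granularity (drop every record of
#' every contributing assay, the default, matching removal of whole
#' assays) or at pair granularity (drop only the records of the
#' conflicting compound-target pairs).
#'
#' @param records An `activity_records` table.
#' @param granularity `"assay"` or `"pair"`.
#' @return The records with conflicts removed; running
#'   [detect_inconsistent_assays()] on the result returns an empty set.
#' @export
resolve_inconsistencies <- function(records, granularity = c("assay", "pair")) {
  granularity <- match.arg(granularity)
  if (granularity == "assay") {
    bad <- detect_inconsistent_assays(records)
    records[!(records$assay_id %in% bad), , drop = FALSE]
  } else {
    dt <- data.table::as.data.table(records)
    conf <- dt[, .(conflict = length(unique(outcome)) > 1),
               by = .(compound_id, target_id)][conflict == TRUE]
    if (nrow(conf) == 0) return(records)
    key <- paste(records$compound_id, records$target_id, sep = "\r")
    records[!(key %in% paste(conf$compound_id, conf$target_id, sep = "\r")), ,
            drop = FALSE]
  }
}
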