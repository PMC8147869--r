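# Compound-level interference screening: PAINS / empirical-liability
# substructure rules and aggregator / firefly-luciferase-inhibitor
# deny-lists, applied after assay curation and before matrix construction.

#' Liability rule set
#'
#' A named filter consisting of SMARTS substructure patterns and/or a
#' deny-list of compound ids. Patterns are validated at construction time
#' (RDKit SMARTS parse), never mid-run.
#'
#' @param name One of `pains`, `chemical_liability`, `aggregator`,
#'   `fluc_inhibitor`.
#' @param patterns Character vector of SMARTS patterns (possibly empty).
#' @param deny_list Character vector of compound ids (possibly empty).
#' @return A list of class `liability_ruleset`.
#' @export
liability_ruleset <- function(name, patterns = character(0),
                              deny_list = character(0)) {
  stopifnot(name %in% c("pains", "chemical_liability", "aggregator",
                        "fluc_inhibitor"))
  patterns <- as.character(patterns)
  if (length(patterns)) {
    res <- chemtools("validate_smarts", list(patterns = as.list(patterns)))
    if (length(res$invalid)) {
      stop("rule set '", name, "': invalid SMARTS pattern(s): ",
           paste(unlist(res$invalid), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, patterns = patterns,
                 deny_list = as.character(deny_list)),
            class = "liability_ruleset")
}

#' Read a liability rule-set file
#'
#' One SMARTS per line with an optional tab-separated name for pattern
#' rule sets, or one compound id per line for deny-lists. Blank lines and
#' `#` comments are ignored.
#'
#' @param name Rule-set name (see [liability_ruleset()]).
#' @param path File path.
#' @param kind `"patterns"` or `"deny_list"`.
#' @return A `liability_ruleset`.
#' @export
read_liability_ruleset <- function(name, path, kind = c("patterns", "deny_list")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  if (kind == "patterns") liability_ruleset(name, patterns = entries)
  else liability_ruleset(name, deny_list = entries)
}

#' Flag compounds against liability rule sets
#'
#' A compound receives a rule set's flag iff it matches at least one of the
#' set's substructure patterns or its id is on the set's deny-list; flags
#' from all rule sets accumulate. Flagging is purely structure/id-based and
#' independent of how many activity records a compound has.
#'
#' @param compounds A `compound_table`.
#' @param rule_sets List of [liability_ruleset()] objects.
#' @return Named list mapping compound id -> character vector of flags
#'   (empty vector when unflagged).
#' @export
flag_compounds <- function(compounds, rule_sets) {
  flags <- stats::setNames(
    replicate(nrow(compounds), character(0), simplify = FALSE),
    compounds$compound_id)
  pattern_sets <- Filter(function(rs) length(rs$patterns) > 0, rule_sets)
  if (length(pattern_sets)) {
    all_patterns <- unlist(lapply(pattern_sets, `[[`, "patterns"))
    set_of_pattern <- rep(vapply(pattern_sets, `[[`, character(1), "name"),
                          vapply(pattern_sets, function(rs) length(rs$patterns),
                                 integer(1)))
    res <- chemtools("match", list(smiles = as.list(compounds$smiles),
                                   patterns = as.list(all_patterns)))
    for (i in seq_len(nrow(compounds))) {
      hit <- res$matches[[i]]
      if (is.null(hit)) {
        stop("unparsable SMILES for compound ", compounds$compound_id[i],
             call. = FALSE)
      }
      hit <- unlist(hit)
      if (any(hit)) {
        flags[[i]] <- unique(c(flags[[i]], set_of_pattern[hit]))
      }
    }
  }
  for (rs in rule_sets) {
    denied <- compounds$compound_id %in% rs$deny_list
    for (i in which(denied)) flags[[i]] <- unique(c(flags[[i]], rs$name))
  }
  flags
}

#' Remove records of flagged compounds
#'
#' Drops every activity record whose compound carries at least one
#' liability flag; the relative order of the surviving records is
#' preserved. Idempotent.
#'
#' @param records An `activity_records` table.
#' @param flags Mapping as returned by [flag_compounds()] (compounds absent
#'   from the mapping are kept).
#' @return The filtered records.
#' @export
remove_flagged <- function(records, flags) {
  flagged <- names(flags)[vapply(flags, length, integer(1)) > 0]
  records[!(records$compound_id %in% flagged), , drop = FALSE]
}
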