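# Reduced-set generation: random removal of half the compound groups, and
# the iterative nearest-neighbor (NN) removal that first eliminates 25% of
# groups by ST-member similarity and then another 25% by MT similarity,
# leaving half the original groups. NN removal probes how nearest-neighbor
# relationships between groups drive MT-versus-ST prediction accuracy.

#' Inter-group structural similarity
#'
#' `mode = "st"`: the maximum Tanimoto similarity over all cross-group
#' pairs of ST members (max-linkage; `linkage = "mean"` averages instead).
#' `mode = "mt"`: the Tanimoto similarity of the two MT compounds.
#'
#' @param g1,g2 Distinct `compound_group` objects.
#' @param mode `"st"` or `"mt"`.
#' @param fingerprints Named list of `fingerprint` objects covering the
#'   required compounds.
#' @param linkage `"max"` (default) or `"mean"`; ST mode only.
#' @return Similarity in `[0, 1]`.
#' @export
group_similarity <- function(g1, g2, mode = c("st", "mt"), fingerprints,
                             linkage = c("max", "mean")) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  stopifnot(g1$group_id != g2$group_id)
  need <- if (mode == "mt") c(g1$mt_compound, g2$mt_compound)
          else c(unname(g1$st_members), unname(g2$st_members))
  missing_fp <- setdiff(need, names(fingerprints))
  if (length(missing_fp)) {
    stop("missing fingerprint for: ", paste(missing_fp, collapse = ", "),
         call. = FALSE)
  }
  if (mode == "mt") {
    return(tanimoto(fingerprints[[g1$mt_compound]],
                    fingerprints[[g2$mt_compound]]))
  }
  sims <- outer(unname(g1$st_members), unname(g2$st_members),
                Vectorize(function(a, b) tanimoto(fingerprints[[a]],
                                                  fingerprints[[b]])))
  if (linkage == "max") max(sims) else mean(sims)
}

# Dense group-by-group similarity matrix for one mode, via the compound
# Tanimoto matrix. Diagonal is NA.
group_similarity_matrix <- function(groups, mode, fingerprints,
                                    linkage = "max") {
  cids <- unique(unlist(lapply(groups, function(g) {
    if (mode == "mt") g$mt_compound else unname(g$st_members)
  })))
  sim_c <- tanimoto_matrix(fingerprints[cids])
  n <- length(groups)
  s <- matrix(NA_real_, n, n)
  member_sets <- lapply(groups, function(g) {
    if (mode == "mt") g$mt_compound else unname(g$st_members)
  })
  agg <- if (identical(linkage, "max")) max else mean
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- agg(sim_c[member_sets[[i]], member_sets[[j]], drop = FALSE])
      s[i, j] <- s[j, i] <- val
    }
  }
  s
}

subset_dataset <- function(dataset, keep_idx, removed_cids = character(0),
                           mark = NULL) {
  marks <- dataset$removal_marks
  if (!is.null(mark)) {
    marks[[mark]] <- sort(unique(c(marks[[mark]], removed_cids)))
  }
  promiscuity_dataset(dataset$groups[keep_idx], name = dataset$name,
                      assay_set = dataset$assay_set,
                      pd_threshold = dataset$pd_threshold,
                      smiles = dataset$smiles,
                      removal_marks = marks)
}

# One NN-removal pass: iteratively take the most similar remaining pair and
# remove, of its two groups, the one whose similarity to its next most
# similar remaining group (the partner excluded) is higher. Ties: top pair
# by lexicographically smallest (group_id_a, group_id_b); next-best tie
# removes the larger group_id.
nn_pass <- function(sim, group_ids, alive, quota) {
  removed <- integer(0)
  while (length(removed) < quota) {
    idx_alive <- which(alive)
    sub <- sim[idx_alive, idx_alive, drop = FALSE]
    top <- max(sub, na.rm = TRUE)
    hits <- which(sub == top & !is.na(sub), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    pair_ids <- cbind(group_ids[idx_alive[hits[, 1]]],
                      group_ids[idx_alive[hits[, 2]]])
    pick <- order(pair_ids[, 1], pair_ids[, 2])[1]
    i <- idx_alive[hits[pick, 1]]
    j <- idx_alive[hits[pick, 2]]
    next_best <- function(g, partner) {
      rest <- setdiff(idx_alive, c(g, partner))
      if (length(rest) == 0) return(-Inf)
      max(sim[g, rest])
    }
    nb_i <- next_best(i, j)
    nb_j <- next_best(j, i)
    drop <- if (nb_i > nb_j) i
            else if (nb_j > nb_i) j
            else if (group_ids[i] > group_ids[j]) i else j
    alive[drop] <- FALSE
    removed <- c(removed, drop)
  }
  list(alive = alive, removed = removed)
}

#' Iterative nearest-neighbor group removal
#'
#' Pass 1 scores group pairs by their most similar ST members and
#' repeatedly removes, from the currently most similar pair, the group
#' with the higher similarity to its next most similar remaining group,
#' until 25% of the original groups are gone. Pass 2 repeats the procedure
#' on the survivors using MT-compound similarity, removing another 25% of
#' the original count, so the final set holds `n0 - 2*ceiling(0.25*n0)`
#' groups. Fully deterministic; invariant to input group order.
#'
#' @param dataset A `promiscuity_dataset` with at least 4 groups.
#' @param fingerprints Named list of `fingerprint` objects for all MT and
#'   ST compounds.
#' @param fraction_per_pass Fraction of the original group count removed
#'   per pass, in (0, 0.5].
#' @param linkage ST-mode linkage, `"max"` (default) or `"mean"`.
#' @return A list: `reduced` (surviving groups), `marked` (the full input
#'   dataset with removed compounds marked `nn_removal_set`), and
#'   `removed` (list of group-id vectors `st_pass`, `mt_pass` in removal
#'   order).
#' @export
nn_removal <- function(dataset, fingerprints, fraction_per_pass = 0.25,
                       linkage = "max") {
  validate_dataset(dataset)
  n0 <- length(dataset$groups)
  if (n0 < 4) stop("nn_removal needs at least 4 groups", call. = FALSE)
  stopifnot(fraction_per_pass > 0, fraction_per_pass <= 0.5)
  quota <- ceiling(fraction_per_pass * n0)
  group_ids <- vapply(dataset$groups, `[[`, integer(1), "group_id")
  ord <- order(group_ids)  # canonical processing order: by group id
  groups <- dataset$groups[ord]
  group_ids <- group_ids[ord]

  sim_st <- group_similarity_matrix(groups, "st", fingerprints, linkage)
  p1 <- nn_pass(sim_st, group_ids, rep(TRUE, n0), quota)

  sim_mt <- group_similarity_matrix(groups, "mt", fingerprints)
  sim_mt[!p1$alive, ] <- NA_real_
  sim_mt[, !p1$alive] <- NA_real_
  p2 <- nn_pass(sim_mt, group_ids, p1$alive, quota)

  removed_idx <- c(p1$removed, p2$removed)
  removed_cids <- unlist(lapply(groups[removed_idx], group_members),
                         use.names = FALSE)
  keep <- which(p2$alive)
  keep_orig <- ord[keep]
  list(
    reduced = subset_dataset(dataset, sort(keep_orig)),
    marked = subset_dataset(dataset, seq_len(n0), removed_cids,
                            mark = "nn_removal_set"),
    removed = list(st_pass = group_ids[p1$removed],
                   mt_pass = group_ids[p2$removed])
  )
}

#' Random group removal
#'
#' Removes a uniform sample (without replacement) of
#' `ceiling(fraction * n0)` groups; reproducible for a given seed.
#'
#' @param dataset A `promiscuity_dataset` with at least 2 groups.
#' @param fraction Fraction of groups to remove, default 0.5.
#' @param seed Integer seed controlling the draw.
#' @return A list like [nn_removal()]: `reduced`, `marked` (with
#'   `random_removal_set` marks) and `removed` (vector of group ids).
#' @export
random_removal <- function(dataset, fraction = 0.5, seed = 1L) {
  validate_dataset(dataset)
  n0 <- length(dataset$groups)
  if (n0 < 2) stop("random_removal needs at least 2 groups", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  k <- ceiling(fraction * n0)
  drop_idx <- withr::with_seed(as.integer(seed), sample.int(n0, k))
  group_ids <- vapply(dataset$groups, `[[`, integer(1), "group_id")
  removed_cids <- unlist(lapply(dataset$groups[drop_idx], group_members),
                         use.names = FALSE)
  list(
    reduced = subset_dataset(dataset, setdiff(seq_len(n0), drop_idx)),
    marked = subset_dataset(dataset, seq_len(n0), removed_cids,
                            mark = "random_removal_set"),
    removed = group_ids[drop_idx]
  )
}

#' Mean nearest-neighbor inter-group similarity
#'
#' For each group, the similarity to its nearest remaining neighbor
#' (ST mode by default), averaged over groups. Used to quantify how much a
#' reduction scheme thinned the dataset's neighbor structure.
#'
#' @param dataset A `promiscuity_dataset` with at least 2 groups.
#' @param fingerprints Named fingerprint list.
#' @param mode `"st"` or `"mt"`.
#' @return Mean of per-group nearest-neighbor similarities.
#' @export
mean_nn_similarity <- function(dataset, fingerprints, mode = "st") {
  stopifnot(length(dataset$groups) >= 2)
  s <- group_similarity_matrix(dataset$groups, mode, fingerprints)
  mean(apply(s, 1, max, na.rm = TRUE))
}
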