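# MT-versus-ST prediction benchmark: fingerprint features, three classifier
# families (RBF-kernel SVM, k-nearest-neighbor with Tanimoto distance,
# random forest), repeated balanced trials scored by balanced accuracy.
# Splitting, class down-sampling and scoring are decided here; classifier
# fit/predict runs in scikit-learn through inst/python/classify.py.

#' Featurize a dataset for classification
#'
#' One fingerprint row per compound, labelled TRUE for the MT member of
#' each group and FALSE for ST members. Row order is deterministic: groups
#' by ascending id, MT row first, then ST rows in target order.
#'
#' @param dataset A `promiscuity_dataset`.
#' @param fingerprints Named list of `fingerprint` objects covering every
#'   compound in the dataset.
#' @return A list with `compound_id` (character), `bits` (list of 0-based
#'   on-bit index vectors), `n_bits`, and `labels` (logical, TRUE = MT).
#' @export
featurize <- function(dataset, fingerprints) {
  validate_dataset(dataset)
  ord <- order(vapply(dataset$groups, `[[`, integer(1), "group_id"))
  cids <- character(0)
  labels <- logical(0)
  for (g in dataset$groups[ord]) {
    cids <- c(cids, group_members(g))
    labels <- c(labels, TRUE, rep(FALSE, length(g$st_members)))
  }
  missing_fp <- setdiff(cids, names(fingerprints))
  if (length(missing_fp)) {
    stop("missing fingerprint for: ",
         paste(utils::head(missing_fp, 5), collapse = ", "), call. = FALSE)
  }
  n_bits <- if (length(cids)) fingerprints[[cids[1]]]$n_bits else 2048L
  list(compound_id = cids,
       bits = lapply(cids, function(id) fingerprints[[id]]$bits),
       n_bits = n_bits,
       labels = labels)
}

#' Balanced accuracy
#'
#' `(sensitivity + specificity) / 2`; robust to class imbalance. Both
#' classes must be present in the reference labels.
#'
#' @param labels Logical (or 0/1) reference labels.
#' @param predictions Logical (or 0/1) predicted labels, same length.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(labels, predictions) {
  labels <- as.logical(labels)
  predictions <- as.logical(predictions)
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("balanced accuracy needs both classes in the labels", call. = FALSE)
  }
  sens <- sum(predictions & labels) / sum(labels)
  spec <- sum(!predictions & !labels) / sum(!labels)
  (sens + spec) / 2
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Run repeated MT-versus-ST classification trials
#'
#' Per trial: the ST class is down-sampled uniformly to the MT count, the
#' balanced set is split into stratified training/test halves, each
#' classifier family is fit on the training half and scored by balanced
#' accuracy on the test half. All randomness derives from `(seed, trial)`,
#' so results are fully reproducible.
#'
#' @param dataset A `promiscuity_dataset` with at least 2 MT and 2 ST
#'   compounds.
#' @param fingerprints Named fingerprint list.
#' @param n_trials Number of independent trials (default 10).
#' @param seed Integer master seed.
#' @param classifiers Subset of `c("svm", "knn", "rf")`.
#' @param train_fraction Fraction of the balanced set used for training.
#' @param params Classifier settings: `svm_cost`, `knn_k`, `rf_trees`.
#' @param permute_labels Permute class labels before training (negative
#'   control; expected balanced accuracy 0.5).
#' @return A list of class `benchmark_result`: `scores` (named list,
#'   classifier -> numeric vector of length `n_trials`), `n_trials`,
#'   `seed`, `params`.
#' @export
run_trials <- function(dataset, fingerprints, n_trials = 10L, seed = 1L,
                       classifiers = c("svm", "knn", "rf"),
                       train_fraction = 0.5,
                       params = list(svm_cost = 1, knn_k = 1, rf_trees = 100),
                       permute_labels = FALSE) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  feat <- featurize(dataset, fingerprints)
  mt_idx <- which(feat$labels)
  st_idx <- which(!feat$labels)
  if (length(mt_idx) < 2 || length(st_idx) < 2) {
    stop("need at least 2 compounds per class", call. = FALSE)
  }
  n_per_class <- min(length(mt_idx), length(st_idx))
  trials <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tseed <- derive_seed(seed, i)
    split <- withr::with_seed(tseed, {
      st_bal <- sample(st_idx, n_per_class)
      mt_bal <- if (length(mt_idx) > n_per_class) sample(mt_idx, n_per_class)
                else mt_idx
      rows <- c(mt_bal, st_bal)
      lab <- feat$labels[rows]
      if (permute_labels) lab <- sample(lab)
      # stratified half split over the balanced subset
      pos <- which(lab); neg <- which(!lab)
      tr <- sort(c(sample(pos, round(train_fraction * length(pos))),
                   sample(neg, round(train_fraction * length(neg)))))
      list(rows = rows, lab = lab, train = tr,
           test = setdiff(seq_along(lab), tr))
    })
    trial <- list(train = as.list(split$rows[split$train] - 1L),
                  test = as.list(split$rows[split$test] - 1L),
                  seed = derive_seed(tseed, 1L))
    if (permute_labels) {
      lab_full <- as.integer(feat$labels)
      lab_full[split$rows] <- as.integer(split$lab)
      trial$labels <- as.list(lab_full)
    }
    trials[[i]] <- trial
    truth[[i]] <- split$lab[split$test]
  }
  res <- run_py("classify.py", character(0), list(
    n_bits = feat$n_bits, rows = feat$bits,
    labels = as.list(as.integer(feat$labels)),
    trials = trials, classifiers = as.list(classifiers), params = params))
  preds <- res$trials
  scores <- stats::setNames(
    lapply(classifiers, function(cl) {
      vapply(seq_len(n_trials), function(i) {
        balanced_accuracy(truth[[i]], unlist(preds[[i]][[cl]]) == 1L)
      }, numeric(1))
    }), classifiers)
  structure(list(scores = scores, n_trials = n_trials, seed = seed,
                 params = params, train_fraction = train_fraction),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("balanced accuracy over", x$n_trials, "trials (median [min, max]):\n")
  for (cl in names(x$scores)) {
    s <- x$scores[[cl]]
    cat(sprintf("  %-4s %.3f [%.3f, %.3f]\n", cl, stats::median(s), min(s),
                max(s)))
  }
  invisible(x)
}

#' Benchmark the original and both reduced dataset variants
#'
#' Runs [run_trials()] on the original dataset, on the random-removal
#' variant and on the nearest-neighbor-removal variant, so the effect of
#' removing nearest-neighbor structure can be compared against removing
#' the same number of groups at random.
#'
#' @inheritParams run_trials
#' @param reduction_seed Seed for the random-removal draw.
#' @return Named list of `benchmark_result` objects:
#'   `original`, `random_removal`, `nn_removal`.
#' @export
benchmark_variants <- function(dataset, fingerprints, n_trials = 10L,
                               seed = 1L, reduction_seed = seed,
                               classifiers = c("svm", "knn", "rf")) {
  rnd <- random_removal(dataset, 0.5, seed = reduction_seed)$reduced
  nn <- nn_removal(dataset, fingerprints, 0.25)$reduced
  list(
    original = run_trials(dataset, fingerprints, n_trials, seed, classifiers),
    random_removal = run_trials(rnd, fingerprints, n_trials, seed, classifiers),
    nn_removal = run_trials(nn, fingerprints, n_trials, seed, classifiers)
  )
}
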