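## Evaluation harness: three-fold cross-validation by repetition,
## forest-size sweeps, and the bad-training-sample (label-noise)
## robustness experiment.

train_and_predict <- function(method, dataset, train_idx, test_idx,
                              config, seed, n_trees, train_labels = NULL) {
  if (is.function(method))
    return(method(dataset, train_idx, test_idx, config, seed))
  switch(method,
    DT = predict(improved_tree(dataset, config = config, seed = seed,
                               pre_classifier = FALSE, subset = train_idx,
                               labels = train_labels),
                 dataset, subset = test_idx),
    IDT = predict(improved_tree(dataset, config = config, seed = seed,
                                pre_classifier = TRUE, subset = train_idx,
                                labels = train_labels),
                  dataset, subset = test_idx),
    RF = predict(slr_forest(dataset, n_trees = n_trees, config = config,
                            seed = seed, subset = train_idx,
                            labels = train_labels),
                 dataset, subset = test_idx),
    stop("unknown method: ", method))
}

method_name <- function(method) {
  if (is.function(method)) "custom" else method
}

#' Three-fold cross-validation by repetition
#'
#' Splits the dataset by its repetition index (each class contributed one
#' sample group per repetition); every fold holds one repetition out for
#' testing and trains on the other two.  Reports per-fold and mean final
#' accuracies per method, plus the accuracies of the intermediate tree
#' stages (handedness and hand orientation) measured on a
#' full-training-set improved tree.
#'
#' @param dataset an `slr_dataset` with a complete repetition structure
#'   (every class present in every repetition).
#' @param methods character vector among `"DT"` (tree without
#'   pre-classifier), `"IDT"`, `"RF"`, or user functions
#'   `f(dataset, train_idx, test_idx, config, seed)` returning test
#'   predictions (useful for harness checks with stub classifiers).
#' @param config an [slr_config()].
#' @param seed RNG seed.
#' @param n_trees forest size for the `"RF"` method.
#' @return an `slr_eval` report.
#' @export
threefold_cv <- function(dataset, methods = c("DT", "IDT", "RF"),
                         config = slr_config(), seed = 1L, n_trees = 30L) {
  dataset <- prepare_features(dataset)
  reps <- sort(unique(dataset$repetition))
  for (r in reps) {
    cov <- unique(dataset$class_id[dataset$repetition == r])
    if (!setequal(cov, unique(dataset$class_id)))
      stop("missing fold coverage: repetition ", r,
           " lacks samples of some class")
  }
  mnames <- vapply(methods, method_name, character(1))
  if (is.character(methods)) methods <- as.list(methods)
  acc <- matrix(NA_real_, length(reps), length(methods),
                dimnames = list(NULL, mnames))
  stage <- matrix(NA_real_, length(reps), 2,
                  dimnames = list(NULL, c("handedness", "orientation")))
  hmap <- vocab_handedness(dataset$vocab)
  for (r in seq_along(reps)) {
    test_idx <- which(dataset$repetition == reps[r])
    train_idx <- which(dataset$repetition != reps[r])
    truth <- dataset$class_id[test_idx]
    for (k in seq_along(methods)) {
      pred <- train_and_predict(methods[[k]], dataset, train_idx, test_idx,
                                config, split_seed(seed, 300, r, k),
                                n_trees)
      acc[r, k] <- mean(pred == truth)
    }
    st_tree <- improved_tree(dataset, config = config,
                             seed = split_seed(seed, 301, r),
                             subset = train_idx)
    det <- predict(st_tree, dataset, subset = test_idx, details = TRUE)
    stage[r, "handedness"] <-
      mean(det$handedness == hmap[as.character(truth)])
    stage[r, "orientation"] <- mean(mapply(function(cand, tc)
      tc %in% cand, det$candidates_after_orientation, truth))
  }
  structure(list(kind = "threefold_cv",
                 per_fold = data.frame(fold = reps, acc,
                                       check.names = FALSE),
                 stage_accuracy = colMeans(stage),
                 mean_accuracy = colMeans(acc),
                 methods = mnames, seed = seed),
            class = "slr_eval")
}

# contaminate per-class training samples: replace k samples of each class
# that has a declared partner with (relabeled) samples of that partner
contaminate <- function(train_idx, train_labels, level, partner_map, seed) {
  local_seed(split_seed(seed, 401), {
    idx <- train_idx
    for (c in as.integer(names(partner_map))) {
      pos <- which(train_labels == c)
      k <- round(level * length(pos))
      if (k == 0) next
      if (k > length(pos))
        stop("replacement count exceeds per-class training samples")
      p <- partner_map[[as.character(c)]]
      src <- train_idx[train_labels == p]
      take <- sample(pos, k)
      idx[take] <- sample(src, k, replace = k > length(src))
    }
    idx  # labels stay: partner signals under the contaminated class label
  })
}

#' Label-noise robustness experiment
#'
#' Emulates bad training samples: for every class with a declared
#' confusable partner, a fraction of its training samples is replaced by
#' (relabeled) samples of the partner.  All methods are trained on the
#' same contaminated training set and tested on the clean held-out
#' repetition; the default split trains on repetitions 1 and 3 and tests
#' on repetition 2.  Error-rate curves per contamination level are
#' averaged over `n_seeds` independent contaminations, and method pairs
#' are compared with the paired Wilcoxon signed-rank test across seeds at
#' each level.
#'
#' @param dataset an `slr_dataset` whose vocabulary declares confusable
#'   pairs.
#' @param levels contamination fractions of the per-class training samples
#'   (default 0, 1/8, ..., 4/8).
#' @param methods see [threefold_cv()].
#' @param n_seeds independent contamination repetitions.
#' @param config an [slr_config()].
#' @param seed base RNG seed.
#' @param n_trees forest size for the `"RF"` method.
#' @param test_repetition repetition held out for testing (default 2).
#' @param pair_direction `"one_way"` (default): per seed, one randomly
#'   chosen member of each confusable pair receives bad samples from its
#'   partner, emulating the asymmetric confusion graph of a real lexicon
#'   (where a sign's confusable partner is itself confusable with further
#'   signs, not only back with the first).  `"both"`: both members are
#'   contaminated symmetrically; note that at the 50% level this makes the
#'   two training distributions of a pair identical, so no classifier can
#'   separate the pair better than chance.
#' @return an `slr_eval` report with per-seed error rates, mean error
#'   curves and Wilcoxon p-values.
#' @export
robustness_experiment <- function(dataset, levels = c(0, 1, 2, 3, 4) / 8,
                                  methods = c("DT", "RF"), n_seeds = 10L,
                                  config = slr_config(), seed = 1L,
                                  n_trees = 30L, test_repetition = 2L,
                                  pair_direction = c("one_way", "both")) {
  pair_direction <- match.arg(pair_direction)
  if (any(levels < 0 | levels > 0.5))
    stop("contamination levels must lie in [0, 0.5]")
  dataset <- prepare_features(dataset)
  pairs <- vocab_pairs(dataset$vocab)
  if (nrow(pairs) == 0) stop("the vocabulary declares no confusable pairs")
  test_idx <- which(dataset$repetition == test_repetition)
  train_idx <- which(dataset$repetition != test_repetition)
  truth <- dataset$class_id[test_idx]
  base_labels <- dataset$class_id[train_idx]
  mnames <- vapply(methods, method_name, character(1))
  if (is.character(methods)) methods <- as.list(methods)

  err <- array(NA_real_, c(n_seeds, length(levels), length(methods)),
               dimnames = list(NULL, paste0("level_", levels), mnames))
  for (s in seq_len(n_seeds)) {
    partner_map <- if (pair_direction == "both") {
      stats::setNames(as.list(c(pairs[, 2], pairs[, 1])),
                      c(pairs[, 1], pairs[, 2]))
    } else {
      flip <- local_seed(split_seed(seed, 499, s),
                         sample(c(TRUE, FALSE), nrow(pairs),
                                replace = TRUE))
      stats::setNames(as.list(ifelse(flip, pairs[, 1], pairs[, 2])),
                      ifelse(flip, pairs[, 2], pairs[, 1]))
    }
    for (li in seq_along(levels)) {
      cidx <- contaminate(train_idx, base_labels, levels[li], partner_map,
                          split_seed(seed, 500, s, li))
      for (k in seq_along(methods)) {
        pred <- train_and_predict(methods[[k]], dataset, cidx, test_idx,
                                  config, split_seed(seed, 501, s, li, k),
                                  n_trees, train_labels = base_labels)
        err[s, li, k] <- mean(pred != truth)
      }
    }
  }
  mean_error <- apply(err, c(2, 3), mean)
  wilcoxon <- NULL
  if (length(methods) >= 2 && n_seeds >= 2) {
    cmb <- utils::combn(length(methods), 2)
    wilcoxon <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      data.frame(method_a = unname(mnames[a]), method_b = unname(mnames[b]),
                 level = levels,
                 p_value = vapply(seq_along(levels), function(li) {
                   d <- err[, li, a] - err[, li, b]
                   if (all(d == 0)) return(1)
                   suppressWarnings(
                     stats::wilcox.test(err[, li, a], err[, li, b],
                                        paired = TRUE)$p.value)
                 }, numeric(1)))
    }))
  }
  structure(list(kind = "robustness", errors = err,
                 mean_error = mean_error, wilcoxon = wilcoxon,
                 levels = levels, methods = mnames, n_seeds = n_seeds,
                 seed = seed),
            class = "slr_eval")
}

#' Recognition accuracy as a function of forest size
#'
#' Trains one forest of `max(sizes)` trees per seed and evaluates every
#' requested size on the prefix of that forest, so a size-k forest is
#' nested in the size-max forest (shared bootstraps reduce sweep
#' variance).  Uses the single train/test split of the robustness
#' experiment.
#'
#' @param dataset an `slr_dataset`.
#' @param sizes forest sizes to evaluate.
#' @param config an [slr_config()].
#' @param seed base RNG seed.
#' @param n_seeds independent forests to average over.
#' @param test_repetition repetition held out for testing.
#' @return an `slr_eval` report with accuracy per size.
#' @export
forest_size_sweep <- function(dataset, sizes = c(1, 5, 10, 20, 30, 40),
                              config = slr_config(), seed = 1L,
                              n_seeds = 5L, test_repetition = 2L) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  sizes <- sort(unique(as.integer(sizes)))
  dataset <- prepare_features(dataset)
  test_idx <- which(dataset$repetition == test_repetition)
  train_idx <- which(dataset$repetition != test_repetition)
  truth <- dataset$class_id[test_idx]
  acc <- matrix(NA_real_, n_seeds, length(sizes),
                dimnames = list(NULL, paste0("trees_", sizes)))
  for (s in seq_len(n_seeds)) {
    forest <- slr_forest(dataset, n_trees = max(sizes), config = config,
                         seed = split_seed(seed, 600, s),
                         subset = train_idx)
    votes <- predict(forest, dataset, subset = test_idx, type = "votes")
    for (j in seq_along(sizes)) {
      pred <- majority_vote(votes[, seq_len(sizes[j]), drop = FALSE])
      acc[s, j] <- mean(pred == truth)
    }
  }
  structure(list(kind = "forest_size_sweep", accuracy = acc,
                 mean_accuracy = colMeans(acc),
                 table = data.frame(n_trees = sizes,
                                    accuracy = colMeans(acc)),
                 sizes = sizes, n_seeds = n_seeds, seed = seed),
            class = "slr_eval")
}

#' @export
print.slr_eval <- function(x, ...) {
  switch(x$kind,
    threefold_cv = {
      cat("Three-fold cross-validation (by repetition)\n")
      print(x$per_fold, row.names = FALSE)
      cat("mean accuracy:",
          paste(names(x$mean_accuracy),
                sprintf("%.4f", x$mean_accuracy), collapse = ", "), "\n")
      cat("stage accuracy: handedness",
          sprintf("%.4f", x$stage_accuracy["handedness"]),
          "| orientation",
          sprintf("%.4f", x$stage_accuracy["orientation"]), "\n")
    },
    robustness = {
      cat("Label-noise robustness (", x$n_seeds, "seeds )\n")
      print(round(x$mean_error, 4))
      if (!is.null(x$wilcoxon)) {
        cat("paired Wilcoxon signed-rank p-values:\n")
        print(x$wilcoxon, row.names = FALSE)
      }
    },
    forest_size_sweep = {
      cat("Forest-size sweep (", x$n_seeds, "seeds )\n")
      print(x$table, row.names = FALSE)
    })
  invisible(x)
}
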