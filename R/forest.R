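## Class-stratified bootstrap bagging of improved decision trees with
## majority voting.  Per the design this emulates, there is no per-node
## feature subsampling: all trees share one structure and differ only
## through their bootstrap samples.

#' Draw a class-stratified bootstrap plan
#'
#' For class `i` with `N_i` training samples, draws `N_i` indices
#' uniformly with replacement from `1..N_i`, so every class keeps its
#' sample count (and its presence) in every bootstrap sample.
#'
#' @param class_counts named integer vector, class id -> `N_i` (all >= 1).
#' @param seed RNG seed.
#' @return named list of index vectors, one per class.
#' @export
#' @examples
#' draw_bootstrap(c(`1` = 3, `2` = 2), seed = 1)
draw_bootstrap <- function(class_counts, seed = 1L) {
  if (any(class_counts < 1)) stop("every class needs at least one sample")
  local_seed(split_seed(seed, 11), {
    out <- lapply(class_counts, function(n)
      sample.int(n, n, replace = TRUE))
    names(out) <- names(class_counts)
    out
  })
}

#' Fit a random forest of improved decision trees
#'
#' Trains `n_trees` improved decision trees, each on its own
#' class-stratified bootstrap resample of the training data, and predicts
#' by majority vote.  Trees are trained independently given their derived
#' seeds, so the fit is identical regardless of training order.
#'
#' @param dataset an `slr_dataset`.
#' @param n_trees number of trees (default 30).
#' @param config an [slr_config()].
#' @param seed RNG seed; tree `t` derives its own seed from `(seed, t)`.
#' @param subset optional training indices into the dataset.
#' @param labels optional label override parallel to `subset`.
#' @param bootstrap draw a bootstrap resample per tree; `FALSE` trains
#'   every tree on the full training set (useful for degeneracy checks).
#' @param pre_classifier,pairs forwarded to [improved_tree()].
#' @return an object of class `slr_forest`.
#' @export
#' @seealso [predict.slr_forest()]
slr_forest <- function(dataset, n_trees = 30L, config = slr_config(),
                       seed = 1L, subset = NULL, labels = NULL,
                       bootstrap = TRUE, pre_classifier = TRUE,
                       pairs = NULL) {
  stopifnot(n_trees >= 1)
  dataset <- prepare_features(dataset)
  idx <- subset %||% seq_along(dataset$segments)
  labels <- labels %||% dataset$class_id[idx]
  classes <- sort(unique(labels))
  by_class <- lapply(classes, function(c) idx[labels == c])
  lab_by_class <- lapply(classes, function(c) labels[labels == c])
  counts <- lengths(by_class)
  names(counts) <- classes

  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    if (bootstrap) {
      plan <- draw_bootstrap(counts, seed = split_seed(seed, 101, t))
      bidx <- unlist(lapply(seq_along(classes), function(k)
        by_class[[k]][plan[[k]]]), use.names = FALSE)
      blab <- unlist(lapply(seq_along(classes), function(k)
        lab_by_class[[k]][plan[[k]]]), use.names = FALSE)
    } else {
      bidx <- idx; blab <- labels
    }
    trees[[t]] <- improved_tree(dataset, config = config,
                                seed = split_seed(seed, 102, t),
                                pre_classifier = pre_classifier,
                                pairs = pairs, subset = bidx,
                                labels = blab)
  }
  structure(list(trees = trees, n_trees = as.integer(n_trees),
                 classes = classes, config = config, seed = seed),
            class = "slr_forest")
}

#' @export
print.slr_forest <- function(x, ...) {
  cat("Random forest of improved decision trees:", x$n_trees, "trees,",
      length(x$classes), "classes\n")
  invisible(x)
}

#' @export
summary.slr_forest <- function(object, ...) {
  cat("Random forest of improved decision trees\n")
  cat("  trees        :", object$n_trees, "\n")
  cat("  classes      :", length(object$classes), "\n")
  cat("  stream weights: ACC", object$config$delta_a, "/ sEMG",
      object$config$delta_e, "\n")
  pc <- object$trees[[1]]$pre_classifier
  cat("  pre-classifier pairs:", if (is.null(pc)) 0 else nrow(pc$pairs),
      "\n")
  invisible(object)
}

#' Majority vote over per-tree predictions
#'
#' Plurality wins; ties are broken toward the lowest class id.
#'
#' @param votes integer matrix, samples x trees.
#' @return integer vector of winning class ids.
#' @export
majority_vote <- function(votes) {
  if (!is.matrix(votes)) votes <- matrix(votes, nrow = 1)
  apply(votes, 1, function(v) {
    tab <- table(v)
    ids <- as.integer(names(tab))
    ids[order(-as.integer(tab), ids)][1]
  })
}

#' Predict subword classes with a random forest
#'
#' @param object an [slr_forest()].
#' @param newdata an `slr_dataset` or list of segments.
#' @param subset optional indices into `newdata`.
#' @param type `"class"` for majority-vote labels, `"votes"` for the full
#'   samples x trees vote matrix.
#' @param ... unused.
#' @return integer vector of class ids, or the vote matrix.
#' @export
predict.slr_forest <- function(object, newdata, subset = NULL,
                               type = c("class", "votes"), ...) {
  type <- match.arg(type)
  feats <- extract_feature_list(newdata, subset)
  votes <- vapply(object$trees, function(tr)
    predict(tr, feats), integer(length(feats)))
  if (length(feats) == 1) votes <- matrix(votes, nrow = 1)
  if (type == "votes") return(votes)
  majority_vote(votes)
}
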