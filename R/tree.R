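## The improved decision tree: pairwise-SVM pre-classifier, one-/two-handed
## SVM, fuzzy K-means hand-orientation stage, and per-class multi-stream
## HMM leaves.  Each stage shrinks the candidate set; the HMMs score only
## the survivors.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classifier configuration
#'
#' Collects the tunable parameters of the decision-tree stages.
#'
#' @param delta_a,delta_e multi-stream fusion weights for the ACC and sEMG
#'   streams (non-negative, summing to 1).
#' @param n_states,n_mix HMM topology: states and Gaussian mixture
#'   components per state.
#' @param hmm_max_iter,hmm_tol Baum-Welch stopping rule.
#' @param normalize_loglik length-normalize per-stream log-likelihoods
#'   before fusion (so the 64-frame ACC stream cannot swamp the shorter
#'   sEMG stream).
#' @param svm_kernel kernel for the pre-classifier and handedness SVMs
#'   (`"linear"` default; `"radial"` available).
#' @param svm_cost SVM cost parameter.
#' @param K_orient number of fuzzy K-means orientation clusters per
#'   handedness branch.
#' @param fuzzifier fuzzy K-means fuzzification exponent m.
#' @param n_pairs number of confusable pairs selected when the training
#'   data carries no declared pairs (`NULL`: floor(n_classes / 2)).
#' @return a list of class `slr_config`.
#' @export
slr_config <- function(delta_a = 0.5, delta_e = 0.5, n_states = 5L,
                       n_mix = 3L, hmm_max_iter = 20L, hmm_tol = 1e-4,
                       normalize_loglik = TRUE, svm_kernel = "linear",
                       svm_cost = 10, K_orient = 8L, fuzzifier = 2,
                       n_pairs = NULL) {
  check_deltas(delta_a, delta_e)
  structure(as.list(environment()), class = "slr_config")
}

# z-scoring fitted on training data; raw sEMG and ACC scales differ by
# orders of magnitude and unscaled SVMs degenerate
fit_scaler <- function(X) {
  s <- apply(X, 2, stats::sd)
  list(center = colMeans(X), scale = pmax(s, 1e-8))
}
apply_scaler <- function(scaler, X) {
  scale(X, center = scaler$center, scale = scaler$scale)
}

#' Rank candidate confusable pairs by feature-space proximity
#'
#' Ranks all class pairs by the ascending Euclidean distance between their
#' class-mean 42-D pre-classifier vectors (on standardized features) and
#' returns the `n_pairs` closest.  This stands in for the expert selection
#' of confusable sign pairs when no pairs are declared by the data source.
#'
#' @param x matrix of pre-classifier vectors (one row per segment) or an
#'   `slr_dataset`.
#' @param labels integer class labels (ignored when `x` is a dataset).
#' @param n_pairs number of pairs to return.
#' @return integer matrix with `n_pairs` rows and columns `class_a`,
#'   `class_b` (a < b), closest first.
#' @export
select_confusable_pairs <- function(x, labels = NULL, n_pairs) {
  if (inherits(x, "slr_dataset")) {
    x <- prepare_features(x)
    labels <- x$class_id
    x <- do.call(rbind, lapply(x$features, function(f) f$pre))
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least 2 classes are required")
  if (n_pairs > choose(length(classes), 2))
    stop("n_pairs exceeds the number of distinct class pairs")
  Z <- apply_scaler(fit_scaler(x), x)
  cm <- t(vapply(classes, function(c)
    colMeans(Z[labels == c, , drop = FALSE]), numeric(ncol(Z))))
  dm <- as.matrix(stats::dist(cm))
  combos <- utils::combn(seq_along(classes), 2)
  d <- dm[t(combos)]
  ord <- order(d)[seq_len(n_pairs)]
  out <- cbind(class_a = classes[combos[1, ord]],
               class_b = classes[combos[2, ord]])
  out
}

# train the bank of pairwise SVMs on 42-D vectors
train_pre_classifier <- function(P, labels, pairs, config) {
  scaler <- fit_scaler(P)
  Z <- apply_scaler(scaler, P)
  svms <- vector("list", nrow(pairs))
  keep <- logical(nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    sel <- labels %in% pairs[j, ]
    y <- factor(labels[sel], levels = pairs[j, ])
    if (nlevels(droplevels(y)) < 2) next  # pair class absent: skip
    keep[j] <- TRUE
    svms[[j]] <- e1071::svm(Z[sel, , drop = FALSE], y,
                            kernel = config$svm_kernel,
                            cost = config$svm_cost, scale = FALSE)
  }
  list(pairs = pairs[keep, , drop = FALSE], svms = svms[keep],
       scaler = scaler)
}

#' Apply the pre-classifier to a candidate set
#'
#' Every pair whose two classes are both still candidates votes through
#' its SVM; the losing class is removed.  Removals that would empty the
#' candidate set are skipped (in pair order), so the set is never emptied.
#'
#' @param pc pre-classifier component of an [improved_tree()] fit.
#' @param v a 42-dimensional pre-classifier vector.
#' @param candidates integer vector of candidate class ids.
#' @return the filtered candidate set.
#' @export
apply_pre_classifier <- function(pc, v, candidates) {
  if (is.null(pc) || length(pc$svms) == 0) return(candidates)
  z <- apply_scaler(pc$scaler, matrix(v, nrow = 1))
  for (j in seq_along(pc$svms)) {
    a <- pc$pairs[j, 1]; b <- pc$pairs[j, 2]
    if (a %in% candidates && b %in% candidates) {
      win <- as.integer(as.character(predict(pc$svms[[j]], z)))
      lose <- if (win == a) b else a
      if (length(candidates) > 1) candidates <- setdiff(candidates, lose)
    }
  }
  candidates
}

#' Train the one-/two-handed separator
#'
#' Fits a maximum-margin hyperplane (linear kernel by default) on the
#' 10-dimensional non-dominant-forearm feature vectors.
#'
#' @param H matrix of handedness vectors (one row per segment).
#' @param handedness character vector, `"one_handed"` / `"two_handed"`.
#' @param config an [slr_config()].
#' @return a separator usable with [classify_handedness()].
#' @export
train_handedness <- function(H, handedness, config = slr_config()) {
  lv <- unique(handedness)
  if (length(lv) < 2) stop("both handedness classes must be present")
  scaler <- fit_scaler(H)
  fit <- e1071::svm(apply_scaler(scaler, H),
                    factor(handedness,
                           levels = c("one_handed", "two_handed")),
                    kernel = config$svm_kernel, cost = config$svm_cost,
                    scale = FALSE)
  structure(list(svm = fit, scaler = scaler), class = "handedness_svm")
}

#' Classify handedness vectors
#'
#' @param separator from [train_handedness()].
#' @param v a 10-dimensional vector or a matrix of them (one per row).
#' @return character vector of `"one_handed"` / `"two_handed"`.
#' @export
classify_handedness <- function(separator, v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  as.character(predict(separator$svm, apply_scaler(separator$scaler, v)))
}

#' Train the hand-orientation stage for one handedness branch
#'
#' Clusters the 3-D dominant-hand ACC mean vectors of the branch by fuzzy
#' K-means and records, per class, every cluster that is the nearest
#' center of at least one of its training samples (the admission map).
#'
#' @param O matrix of orientation vectors (one row per segment).
#' @param class_id integer labels parallel to the rows of `O`.
#' @param K number of clusters (reduced to the number of distinct vectors
#'   when necessary; must not exceed the branch sample count).
#' @param m fuzzification exponent.
#' @param seed RNG seed for center initialization.
#' @return an `orientation_model`: cluster centers plus the
#'   class-to-cluster admission map.
#' @export
train_orientation <- function(O, class_id, K = 8L, m = 2, seed = 1L) {
  n <- nrow(O)
  if (K > n) stop("K exceeds the branch sample count")
  K <- min(K, nrow(unique(O)))
  membership <- NULL
  if (K < 2) {
    centers <- matrix(colMeans(O), 1)
    membership <- matrix(1, n, 1)
  } else {
    cm <- local_seed(seed,
      e1071::cmeans(O, centers = K, m = m, iter.max = 100))
    centers <- cm$centers
    membership <- cm$membership
  }
  cl <- nearest_center(centers, O)
  admitted <- lapply(seq_len(nrow(centers)), function(k)
    sort(unique(class_id[cl == k])))
  structure(list(centers = centers, admitted = admitted, K = nrow(centers),
                 membership = membership,
                 classes = sort(unique(class_id))),
            class = "orientation_model")
}

nearest_center <- function(centers, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
    2 * X %*% t(centers)
  max.col(-d2, ties.method = "first")
}

#' Assign an orientation vector to its nearest cluster
#'
#' Nearest-centroid by Euclidean distance; the candidate set is then meant
#' to be intersected with the classes admitted at that cluster.
#'
#' @param model an `orientation_model`.
#' @param v a 3-D orientation vector (or a matrix of them).
#' @return list with `cluster` (integer vector) and `classes` (list of
#'   admitted class sets).
#' @export
classify_orientation <- function(model, v) {
  cl <- nearest_center(model$centers, v)
  list(cluster = cl, classes = model$admitted[cl])
}

#' Fit an improved decision tree
#'
#' The hierarchical classifier: (1) a pre-classifier of pairwise SVMs that
#' removes the losing member of every confusable pair still in play,
#' (2) a one-/two-handed SVM on the non-dominant forearm features,
#' (3) a fuzzy K-means hand-orientation stage per handedness branch, and
#' (4) per-class multi-stream Gaussian-mixture HMMs scoring the surviving
#' candidates.  Omitting the pre-classifier (`pre_classifier = FALSE`)
#' reproduces the plain decision tree this design improves on.
#'
#' @param dataset an `slr_dataset` (features are computed and cached on
#'   first use).
#' @param config an [slr_config()].
#' @param seed RNG seed controlling HMM and cluster initialization.
#' @param pre_classifier include the pairwise pre-classifier stage.
#' @param pairs optional explicit pair matrix (columns `class_a`,
#'   `class_b`); default: the vocabulary's declared confusable pairs,
#'   falling back to distance-ranked selection.
#' @param subset optional training indices into the dataset (bootstrap
#'   resamples may repeat indices).
#' @param labels optional label override parallel to `subset` (used by the
#'   label-noise robustness experiment).
#' @return an object of class `improved_tree`.
#' @seealso [predict.improved_tree()], [slr_forest()]
#' @export
improved_tree <- function(dataset, config = slr_config(), seed = 1L,
                          pre_classifier = TRUE, pairs = NULL,
                          subset = NULL, labels = NULL) {
  dataset <- prepare_features(dataset)
  idx <- subset %||% seq_along(dataset$segments)
  labels <- labels %||% dataset$class_id[idx]
  stopifnot(length(labels) == length(idx))
  feats <- dataset$features[idx]
  classes <- sort(unique(labels))
  hmap <- vocab_handedness(dataset$vocab)

  P <- do.call(rbind, lapply(feats, function(f) f$pre))
  H <- do.call(rbind, lapply(feats, function(f) f$hand10))
  O <- do.call(rbind, lapply(feats, function(f) f$orient))

  pc <- NULL
  if (pre_classifier) {
    if (is.null(pairs)) {
      pairs <- vocab_pairs(dataset$vocab)
      if (nrow(pairs) == 0) {
        np <- config$n_pairs %||% floor(length(classes) / 2)
        if (np > 0) pairs <- select_confusable_pairs(P, labels, np)
      }
    }
    pairs <- pairs[pairs[, 1] %in% classes & pairs[, 2] %in% classes, ,
                   drop = FALSE]
    if (nrow(pairs) > 0) pc <- train_pre_classifier(P, labels, pairs, config)
  }

  hand_lab <- unname(hmap[as.character(labels)])
  handedness <- if (length(unique(hand_lab)) >= 2)
    train_handedness(H, hand_lab, config)
  else structure(list(constant = unique(hand_lab)),
                 class = "handedness_svm")

  orientation <- list(one_handed = NULL, two_handed = NULL)
  for (br in c("one_handed", "two_handed")) {
    sel <- hand_lab == br
    if (any(sel)) {
      orientation[[br]] <- train_orientation(
        O[sel, , drop = FALSE], labels[sel],
        K = min(config$K_orient, sum(sel)), m = config$fuzzifier,
        seed = split_seed(seed, 31, match(br, c("one_handed", "two_handed"))))
    }
  }

  hmms <- list()
  for (c in classes) {
    sel <- which(labels == c)
    two <- hmap[as.character(c)] == "two_handed"
    fit_streams <- function(obs_name, salt) {
      list(A = hmm_fit(lapply(feats[sel], function(f) f[[obs_name]]$O_A),
                       n_states = config$n_states, n_mix = config$n_mix,
                       max_iter = config$hmm_max_iter, tol = config$hmm_tol,
                       seed = split_seed(seed, 41, c, salt)),
           E = hmm_fit(lapply(feats[sel], function(f) f[[obs_name]]$O_E),
                       n_states = config$n_states, n_mix = config$n_mix,
                       max_iter = config$hmm_max_iter, tol = config$hmm_tol,
                       seed = split_seed(seed, 42, c, salt)))
    }
    hmms[[as.character(c)]] <- list(
      handedness = unname(hmap[as.character(c)]),
      R = fit_streams("obs_dom", 1),
      L = if (two) fit_streams("obs_ndom", 2) else NULL)
  }

  structure(list(classes = classes, pre_classifier = pc,
                 handedness = handedness, orientation = orientation,
                 hmms = hmms, hmap = hmap[as.character(classes)],
                 config = config, seed = seed,
                 n_train = length(idx)),
            class = "improved_tree")
}

#' @export
print.improved_tree <- function(x, ...) {
  cat("Improved decision tree:", length(x$classes), "classes,",
      if (is.null(x$pre_classifier)) "no pre-classifier"
      else paste(nrow(x$pre_classifier$pairs), "pre-classifier pair(s)"),
      "\n")
  invisible(x)
}

# score one sample's surviving candidates with the multi-stream HMM leaves
hmm_stage <- function(tree, cand, f) {
  cfg <- tree$config
  scores <- vapply(cand, function(c) {
    m <- tree$hmms[[as.character(c)]]
    s <- hand_score(m$R, f$obs_dom, cfg$delta_a, cfg$delta_e,
                    cfg$normalize_loglik)
    if (!is.null(m$L))
      s <- s + hand_score(m$L, f$obs_ndom, cfg$delta_a, cfg$delta_e,
                          cfg$normalize_loglik)
    s
  }, numeric(1))
  cand[order(-scores, cand)][1]
}

#' Predict subword classes with an improved decision tree
#'
#' Applies the four stages in order; each stage can only shrink the
#' candidate set and a filter that would empty it is skipped, so the set
#' is never empty when it reaches the HMM leaves.
#'
#' @param object an [improved_tree()].
#' @param newdata an `slr_dataset` or a list of `subword_segment`s.
#' @param subset optional indices into `newdata`.
#' @param details also return per-sample stage diagnostics.
#' @param ... unused.
#' @return integer vector of predicted class ids, or (with
#'   `details = TRUE`) a list with `class`, `handedness`,
#'   `orientation_cluster` and `candidates_after_orientation`.
#' @export
predict.improved_tree <- function(object, newdata, subset = NULL,
                                  details = FALSE, ...) {
  feats <- extract_feature_list(newdata, subset)
  n <- length(feats)
  P <- do.call(rbind, lapply(feats, function(f) f$pre))
  H <- do.call(rbind, lapply(feats, function(f) f$hand10))
  O <- do.call(rbind, lapply(feats, function(f) f$orient))
  cand <- replicate(n, object$classes, simplify = FALSE)

  # stage 1: pre-classifier (batched SVM votes)
  pc <- object$pre_classifier
  if (!is.null(pc) && length(pc$svms) > 0) {
    Z <- apply_scaler(pc$scaler, P)
    for (j in seq_along(pc$svms)) {
      a <- pc$pairs[j, 1]; b <- pc$pairs[j, 2]
      win <- as.integer(as.character(predict(pc$svms[[j]], Z)))
      for (i in seq_len(n)) {
        if (a %in% cand[[i]] && b %in% cand[[i]] && length(cand[[i]]) > 1) {
          lose <- if (win[i] == a) b else a
          cand[[i]] <- setdiff(cand[[i]], lose)
        }
      }
    }
  }

  # stage 2: one-/two-handed SVM
  hpred <- if (!is.null(object$handedness$constant))
    rep(object$handedness$constant, n)
  else classify_handedness(object$handedness, H)
  for (i in seq_len(n)) {
    keep <- cand[[i]][object$hmap[as.character(cand[[i]])] == hpred[i]]
    if (length(keep) > 0) cand[[i]] <- keep
  }

  # stage 3: hand orientation (nearest fuzzy K-means center per branch)
  ocl <- integer(n)
  for (br in c("one_handed", "two_handed")) {
    om <- object$orientation[[br]]
    sel <- which(hpred == br)
    if (is.null(om) || length(sel) == 0) next
    res <- classify_orientation(om, O[sel, , drop = FALSE])
    ocl[sel] <- res$cluster
    for (k in seq_along(sel)) {
      i <- sel[k]
      keep <- intersect(cand[[i]], res$classes[[k]])
      if (length(keep) > 0) cand[[i]] <- keep
    }
  }
  cand_orient <- cand

  # stage 4: multi-stream HMM scoring of the survivors
  pred <- vapply(seq_len(n), function(i)
    hmm_stage(object, cand[[i]], feats[[i]]), integer(1))

  if (details)
    list(class = pred, handedness = hpred, orientation_cluster = ocl,
         candidates_after_orientation = cand_orient)
  else pred
}

extract_feature_list <- function(newdata, subset = NULL) {
  if (inherits(newdata, "slr_dataset")) {
    newdata <- prepare_features(newdata)
    feats <- newdata$features
  } else if (inherits(newdata, "subword_segment")) {
    feats <- list(segment_features(newdata))
  } else if (is.list(newdata)) {
    feats <- lapply(newdata, function(s)
      if (inherits(s, "subword_segment")) segment_features(s) else s)
  } else stop("newdata must be an slr_dataset or a list of segments")
  if (!is.null(subset)) feats <- feats[subset]
  feats
}
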