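test_that("confusable-pair selection ranks close class pairs first", {
  ds <- small_dataset()
  declared <- slrforest:::vocab_pairs(ds$vocab)
  top <- select_confusable_pairs(ds, n_pairs = 2)
  norm <- function(p) apply(p, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(norm(top), norm(declared))

  # two classes: the single possible pair
  X <- matrix(rnorm(40), 10, 4)
  lab <- rep(1:2, each = 5)
  expect_equal(unname(select_confusable_pairs(X, lab, 1)[1, ]), c(1, 2))
  expect_error(select_confusable_pairs(X, lab, 2), "exceeds")
  expect_error(select_confusable_pairs(X, rep(1, 10), 1), "2 classes")

  # duplicated classes have distance 0 and rank first
  X3 <- rbind(X, X[lab == 2, ] + 50)
  lab3 <- c(lab, rep(3, 5))
  X4 <- rbind(X3, X3[lab3 == 3, ])
  lab4 <- c(lab3, rep(4, 5))
  expect_equal(sort(unname(select_confusable_pairs(X4, lab4, 1)[1, ])),
               c(3, 4))
})

test_that("pre-classifier votes remove pair losers and never empty the
           candidate set", {
  ds <- small_dataset()
  P <- do.call(rbind, lapply(ds$features, function(f) f$pre))
  pairs <- slrforest:::vocab_pairs(ds$vocab)
  pc <- slrforest:::train_pre_classifier(P, ds$class_id, pairs,
                                         slr_config())
  v <- ds$features[[1]]$pre
  full <- sort(unique(ds$class_id))
  # no pairs -> identity
  expect_equal(apply_pre_classifier(NULL, v, full), full)
  out <- apply_pre_classifier(pc, v, full)
  expect_true(all(out %in% full))
  expect_equal(length(out), length(full) - nrow(pairs))
  # classes outside any surviving pair are untouched
  unpaired <- setdiff(full, c(pairs))
  expect_true(all(unpaired %in% out))
  # candidate set of one member only: its pair cannot vote
  a <- pairs[1, 1]
  expect_equal(apply_pre_classifier(pc, v, a), a)
  # the guard never empties a two-member set down to zero
  both <- sort(pairs[1, ])
  expect_equal(length(apply_pre_classifier(pc, v, both)), 1)
})

test_that("the handedness separator is max-margin on its training set and
           classifies rest-like vectors as one-handed", {
  ds <- small_dataset()
  H <- do.call(rbind, lapply(ds$features, function(f) f$hand10))
  h <- vocab_handedness_of(ds)[as.character(ds$class_id)]
  sep <- train_handedness(H, h)
  expect_equal(mean(classify_handedness(sep, H) == h), 1)  # separable
  expect_error(train_handedness(H, rep("one_handed", nrow(H))), "both")
  # all-zero sEMG MAVs, rest-gravity mean, zero ACC spread -> one-handed
  rest <- c(rep(0, 4), 0, 0, 1, rep(0, 3))
  expect_equal(classify_handedness(sep, rest), "one_handed")
})

test_that("fuzzy K-means orientation clustering is pure on well-separated
           gravity groups and admits every class somewhere", {
  set.seed(1)
  ov <- orientation_vectors()
  O <- ov[rep(1:8, each = 30), ] + matrix(rnorm(8 * 30 * 3, sd = 0.05),
                                          240, 3)
  cls <- rep(1:8, each = 30)
  om <- train_orientation(O, cls, K = 8, seed = 2)
  cl <- classify_orientation(om, O)$cluster
  purity <- mean(vapply(1:8, function(k) {
    sel <- cl == k
    if (!any(sel)) return(1)
    max(table(cls[sel])) / sum(sel)
  }, numeric(1)))
  expect_gte(purity, 0.95)
  expect_setequal(sort(unique(unlist(om$admitted))), 1:8)
  expect_equal(unname(rowSums(om$membership)), rep(1, 240),
               tolerance = 1e-9)
  expect_error(train_orientation(O[1:4, ], cls[1:4], K = 8), "sample count")
  # K = 1 degenerates to an identity filter
  om1 <- train_orientation(O, cls, K = 1)
  expect_equal(classify_orientation(om1, O[1, ])$classes[[1]], 1:8)
})

test_that("candidate sets shrink monotonically, never empty, and every
           class stays reachable", {
  ds <- small_dataset()
  tr <- improved_tree(ds, seed = 3)
  det <- predict(tr, ds, details = TRUE)
  for (cand in det$candidates_after_orientation) {
    expect_gt(length(cand), 0)
    expect_true(all(cand %in% tr$classes))
  }
  # orientation admission covers the vocabulary
  adm <- c(unlist(tr$orientation$one_handed$admitted),
           unlist(tr$orientation$two_handed$admitted))
  expect_setequal(sort(unique(adm)), tr$classes)
  expect_true(all(det$class %in% tr$classes))
})

test_that("removing the pre-classifier reproduces the baseline tree's
           later stages exactly", {
  ds <- small_dataset()
  idt <- improved_tree(ds, seed = 11, pre_classifier = TRUE)
  dt <- improved_tree(ds, seed = 11, pre_classifier = FALSE)
  expect_null(dt$pre_classifier)
  # later stages are trained identically (same seeds, same data)
  d1 <- predict(idt, ds, details = TRUE)
  d2 <- predict(dt, ds, details = TRUE)
  expect_identical(d1$handedness, d2$handedness)
  expect_identical(d1$orientation_cluster, d2$orientation_cluster)
})

test_that("a single-class tree always returns that class", {
  ds <- small_dataset()
  idx <- which(ds$class_id == 2)
  tr <- improved_tree(ds, subset = idx, seed = 1)
  expect_equal(unique(predict(tr, ds)), 2L)
})

test_that("the improved tree beats or matches the plain tree on held-out
           confusable-pair data", {
  ds <- small_dataset()
  train <- which(ds$repetition != 2)
  test <- which(ds$repetition == 2)
  truth <- ds$class_id[test]
  accs <- vapply(1:3, function(s) {
    c(idt = mean(predict(improved_tree(ds, subset = train, seed = s),
                         ds, subset = test) == truth),
      dt = mean(predict(improved_tree(ds, subset = train, seed = s,
                                      pre_classifier = FALSE),
                        ds, subset = test) == truth))
  }, numeric(2))
  expect_gte(mean(accs["idt", ]), mean(accs["dt", ]) - 0.005)
})
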