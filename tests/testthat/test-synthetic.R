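test_that("make_vocabulary validates inputs and keeps its bookkeeping", {
  expect_error(make_vocabulary(1), "n_classes")
  expect_error(make_vocabulary(4, frac_two_handed = 1.2), "frac_two_handed")
  expect_error(make_vocabulary(4, n_confusable_pairs = 3), "confusable")

  v2 <- make_vocabulary(2, n_confusable_pairs = 1, frac_two_handed = 0,
                        seed = 1)
  expect_length(v2, 2)
  expect_true(all(vapply(v2, function(s) s$handedness, character(1)) ==
                    "one_handed"))
  expect_equal(v2[[1]]$confusable_with, 2L)
  expect_equal(v2[[2]]$confusable_with, 1L)

  v20 <- make_vocabulary(20, n_confusable_pairs = 8, frac_two_handed = 0.5,
                         seed = 7)
  expect_length(v20, 20)
  expect_equal(sum(vapply(v20, function(s) s$handedness, character(1)) ==
                     "two_handed"), 10)
  pairs <- vocab_pairs_of(v20)
  expect_equal(nrow(pairs), 8)
  for (r in seq_len(nrow(pairs))) {  # links are mutual and share handedness
    a <- v20[[pairs[r, 1]]]; b <- v20[[pairs[r, 2]]]
    expect_equal(a$confusable_with, b$class_id)
    expect_equal(a$handedness, b$handedness)
    expect_equal(a$orientation_id, b$orientation_id)
  }
})

test_that("orientation ids cover all 8 groups over many generated specs", {
  v <- make_vocabulary(1000, seed = 11)
  ids <- vapply(v, function(s) s$orientation_id, integer(1))
  expect_setequal(unique(ids), 0:7)
})

test_that("spec invariants hold: stable AR shaping, quiet non-dominant
           channels for one-handed, duration floor", {
  v <- make_vocabulary(30, n_confusable_pairs = 10, seed = 3)
  for (s in v) {
    for (c in 1:8) {
      if (s$gains[c] > 0)
        expect_true(all(Mod(polyroot(c(rev(s$ar[c, ]), 1))) < 1))
    }
    expect_gte(s$duration_ms, 640)
    if (s$handedness == "one_handed") {
      expect_true(all(s$gains[5:8] == 0))
      expect_true(all(s$traj[4:6, "amp"] == 0))
    }
  }
})

test_that("synthesis is deterministic given (spec, seed)", {
  v <- make_vocabulary(3, seed = 2)
  r1 <- synthesize_subword(v[[1]], seed = 9)
  r2 <- synthesize_subword(v[[1]], seed = 9)
  expect_identical(r1, r2)
  r3 <- synthesize_subword(v[[1]], seed = 10)
  expect_false(identical(r1$emg, r3$emg))
})

test_that("one-handed subwords are quiet on the non-dominant side and
           active on the dominant side", {
  v <- make_vocabulary(4, frac_two_handed = 0, seed = 5)
  nf <- 0.05
  rec <- synthesize_subword(v[[1]], seed = 1, noise_floor = nf)
  ann <- rec$annotations
  act <- (ann$t_start + 1):(ann$t_end + 1)
  mav_nd <- apply(rec$emg[act, 5:8], 2, function(x) mean(abs(x)))
  mav_d <- apply(rec$emg[act, 1:4], 2, function(x) mean(abs(x)))
  expect_true(all(mav_nd < 3 * nf))
  expect_true(all(mav_d > 10 * nf))
})

test_that("with zero trajectory and zero noise the ACC channels reproduce
           the gravity projection exactly", {
  v <- make_vocabulary(2, seed = 8)
  s <- v[[1]]
  s$traj[, "amp"] <- 0
  s$orientation_id <- 4L  # +z
  s <- do.call(subword_spec, unclass(s))
  rec <- synthesize_subword(s, seed = 3, acc_noise = 0, g_scale = 2,
                            jitter = 0)
  expect_equal(unname(rec$acc[, "accRz"]),
               rep(2, nrow(rec$acc)), tolerance = 1e-12)
  expect_true(all(abs(rec$acc[, c("accRx", "accRy")]) < 1e-12))
})

test_that("the AR(4) shaping of a long constant-envelope sEMG channel is
           recovered by LPC within 0.05 per coefficient", {
  v <- make_vocabulary(2, seed = 21)
  s <- v[[1]]
  s$duration_ms <- 120000  # long constant-envelope burst
  s$env_floor <- 1
  s <- do.call(subword_spec, unclass(s))
  rec <- synthesize_subword(s, seed = 4, jitter = 0, noise_floor = 0.02)
  ann <- rec$annotations
  x <- rec$emg[(ann$t_start + 1):(ann$t_end + 1), 1]
  expect_gte(length(x), 1e5)
  est <- lpc(x, 4)
  expect_true(all(abs(est - s$ar[1, ]) < 0.05))
})

test_that("sentences concatenate subwords with epenthesis gaps and full
           ground truth", {
  v <- make_vocabulary(4, seed = 6)
  rec <- synthesize_sentence(v, gap_ms = 500, seed = 2)
  ann <- rec$annotations
  expect_equal(nrow(ann), 4)
  expect_equal(ann$class_id, 1:4)
  gaps <- ann$t_start[-1] - ann$t_end[-4]
  expect_true(all(gaps >= 500))
  expect_true(all(diff(ann$t_start) > 0))  # sorted, non-overlapping

  # degenerate case: a 1-spec sentence shares the subword's active region
  r1 <- synthesize_sentence(v[1], gap_ms = 400, seed = 2)
  rs <- synthesize_subword(v[[1]], seed = 2)
  a1 <- r1$annotations; as <- rs$annotations
  expect_equal(a1$t_end - a1$t_start, as$t_end - as$t_start)
  expect_equal(r1$emg[(a1$t_start + 1):(a1$t_end + 1), ],
               rs$emg[(as$t_start + 1):(as$t_end + 1), ])
  expect_error(synthesize_sentence(list(), seed = 1), "at least one")
  expect_error(synthesize_sentence(v, gap_ms = 100, seed = 1), "gap_ms")
})

test_that("make_dataset produces the requested shape, bit-identical under
           the same seed, with ACC means clustered by orientation", {
  v <- make_vocabulary(5, seed = 9)
  ds <- make_dataset(v, reps_per_class = 6, seed = 3)
  expect_length(ds$segments, 30)
  expect_equal(as.vector(table(ds$class_id)), rep(6L, 5))
  expect_equal(as.vector(table(ds$repetition)), rep(10L, 3))
  ds2 <- make_dataset(v, reps_per_class = 6, seed = 3)
  expect_identical(ds[c("segments", "class_id", "repetition")],
                   ds2[c("segments", "class_id", "repetition")])

  # class-conditional dominant ACC means sit near the class's gravity vector
  ov <- orientation_vectors()
  for (i in seq_along(v)) {
    segs <- ds$segments[ds$class_id == i]
    m <- colMeans(t(vapply(segs, function(s) colMeans(s$acc[, 1:3]),
                           numeric(3))))
    d <- sqrt(colSums((t(ov) - m)^2))
    expect_equal(unname(which.min(d)) - 1L, v[[i]]$orientation_id)
  }
})

test_that("handedness vectors of one- and two-handed subwords are linearly
           separable", {
  ds <- small_dataset()
  H <- do.call(rbind, lapply(ds$features, function(f) f$hand10))
  h <- vocab_handedness_of(ds)[as.character(ds$class_id)]
  sep <- train_handedness(H, h)
  acc <- mean(classify_handedness(sep, H) == h)
  expect_gte(acc, 0.99)
})

test_that("increasing the confusable-pair perturbation scale makes the
           pairwise SVM stage strictly more accurate", {
  accs <- vapply(c(0.02, 0.1, 0.25), function(sc) {
    v <- make_vocabulary(2, n_confusable_pairs = 1, frac_two_handed = 0,
                         seed = 13, perturb_scale = sc)
    tr <- make_dataset(v, reps_per_class = 12, seed = 100)
    te <- make_dataset(v, reps_per_class = 100, seed = 200)
    Ptr <- t(vapply(tr$segments, build_preclassifier_vector, numeric(42)))
    Pte <- t(vapply(te$segments, build_preclassifier_vector, numeric(42)))
    pc <- slrforest:::train_pre_classifier(Ptr, tr$class_id,
                                           cbind(1L, 2L), slr_config())
    z <- slrforest:::apply_scaler(pc$scaler, Pte)
    pred <- as.integer(as.character(predict(pc$svms[[1]], z)))
    mean(pred == te$class_id)
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
  expect_lt(accs[1], accs[3])
})
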