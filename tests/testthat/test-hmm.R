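test_that("forward log-likelihood of a 1-state model is the summed mixture
           log-density", {
  h <- random_hmm(1, 2, 3, seed = 1)
  m <- cont_hmm_from(h)
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  direct <- sum(vapply(1:5, function(t) {
    log(sum(vapply(1:2, function(k)
      h$w[1, k] * prod(dnorm(X[t, ], h$means[, k, 1],
                             sqrt(h$vars[, k, 1]))), numeric(1))))
  }, numeric(1)))
  expect_equal(hmm_loglik(m, X), direct, tolerance = 1e-12)
})

test_that("forward algorithm equals exhaustive path enumeration on small
           models", {
  for (k in 1:20) {
    set.seed(k)
    S <- sample(2:3, 1); M <- sample(1:2, 1); D <- sample(1:2, 1)
    Tn <- sample(2:4, 1)
    h <- random_hmm(S, M, D, seed = 100 + k)
    X <- matrix(rnorm(Tn * D), Tn, D)
    ours <- hmm_loglik(cont_hmm_from(h), X)
    brute <- brute_loglik(h$pi, h$A, h$w, h$means, h$vars, X)
    expect_equal(ours, brute, tolerance = 1e-9)
  }
})

test_that("forward log-likelihood is invariant under state relabeling", {
  h <- random_hmm(4, 2, 3, seed = 9)
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  base <- hmm_loglik(cont_hmm_from(h), X)
  for (r in 1:5) {
    p <- sample(4)
    hp <- list(pi = h$pi[p], A = h$A[p, p], w = h$w[p, , drop = FALSE],
               means = h$means[, , p, drop = FALSE],
               vars = h$vars[, , p, drop = FALSE])
    expect_equal(hmm_loglik(cont_hmm_from(hp), X), base,
                 tolerance = 1e-10)
  }
  expect_error(hmm_loglik(cont_hmm_from(h), X[, 1:2]), "dimension")
})

test_that("Baum-Welch log-likelihood is non-decreasing on seeded runs", {
  for (k in 1:5) {
    h <- random_hmm(2, 1, 1, seed = 20 + k)
    seqs <- simulate_hmm(h, n_seq = 10, len = 30, seed = 30 + k)
    fit <- hmm_fit(seqs, n_states = 2, n_mix = 2, max_iter = 15, tol = 0,
                   seed = k)
    tr <- fit$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("Baum-Welch recovers the states of a known 2-state model", {
  truth <- list(pi = c(1, 0), A = rbind(c(0.94, 0.06), c(0, 1)),
                w = matrix(1, 2, 1),
                means = array(c(-2, 2), c(1, 1, 2)),
                vars = array(c(0.25, 0.25), c(1, 1, 2)))
  seqs <- simulate_hmm(truth, n_seq = 200, len = 50, seed = 77)
  fit <- hmm_fit(seqs, n_states = 2, n_mix = 1, max_iter = 30, tol = 1e-8,
                 seed = 5)
  est <- sort(as.numeric(fit$means))
  expect_equal(est, c(-2, 2), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(fit$A[1, 1], 0.94, tolerance = 0.1)
})

test_that("a single constant sequence collapses to a point mass with the
           variance at its floor", {
  X <- matrix(3, 40, 2)
  fit <- hmm_fit(list(X), n_states = 1, n_mix = 1, max_iter = 5, seed = 1)
  expect_equal(as.numeric(fit$means), c(3, 3), tolerance = 1e-9)
  expect_equal(as.numeric(fit$vars), fit$var_floor, tolerance = 1e-12)
  expect_error(hmm_fit(list(X[1:3, ]), n_states = 5), "n_states")
  expect_error(hmm_fit(list(), n_states = 1), "one training sequence")
})

test_that("fitted models satisfy the stochasticity and covariance-floor
           invariants", {
  ds <- small_dataset()
  idx <- which(ds$class_id == 1)
  seqs <- lapply(ds$features[idx], function(f) f$obs_dom$O_E)
  fit <- hmm_fit(seqs, seed = 3)
  expect_equal(rowSums(fit$A), rep(1, 5), tolerance = 1e-9)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$w), rep(1, 5), tolerance = 1e-9)
  expect_true(all(fit$vars >= array(fit$var_floor,
                                    dim(fit$vars)) - 1e-15))
  # left-to-right structure is preserved by EM
  expect_true(all(fit$A[lower.tri(fit$A)] == 0))
})

test_that("multi-stream fusion weights and tie-breaks behave as stated", {
  ds <- small_dataset()
  f1 <- ds$features[[1]]
  seqsA <- lapply(ds$features[ds$class_id == 1], function(f) f$obs_dom$O_A)
  seqsE <- lapply(ds$features[ds$class_id == 1], function(f) f$obs_dom$O_E)
  mA <- hmm_fit(seqsA, seed = 1); mE <- hmm_fit(seqsE, seed = 2)
  seqsA2 <- lapply(ds$features[ds$class_id == 2], function(f) f$obs_dom$O_A)
  seqsE2 <- lapply(ds$features[ds$class_id == 2], function(f) f$obs_dom$O_E)
  models <- list(`1` = list(A = mA, E = mE),
                 `2` = list(A = hmm_fit(seqsA2, seed = 3),
                            E = hmm_fit(seqsE2, seed = 4)))
  # weight degeneracy: delta_A = 1 ranks by the ACC stream alone
  s1 <- score_one_handed(models, f1$obs_dom, delta_a = 1, delta_e = 0)
  acconly <- vapply(models, function(m)
    hmm_loglik(m$A, f1$obs_dom$O_A) / nrow(f1$obs_dom$O_A), numeric(1))
  expect_equal(order(s1$scores), order(acconly))
  # identical models tie; ties break to the lowest class id
  tied <- list(`7` = models[[1]], `3` = models[[1]])
  expect_equal(score_one_handed(tied, f1$obs_dom)$class, 3L)
  expect_error(score_one_handed(list(), f1$obs_dom), "empty")
  expect_error(score_one_handed(models, f1$obs_dom, 0.7, 0.6), "sum to 1")
  # two-handed scoring doubles one-handed scores for identical hands
  two <- list(`1` = list(R = models[[1]], L = models[[1]]),
              `2` = list(R = models[[2]], L = models[[2]]))
  s2 <- score_two_handed(two, f1$obs_dom, f1$obs_dom)
  expect_equal(s2$class, score_one_handed(models, f1$obs_dom)$class)
  expect_equal(unname(s2$scores),
               unname(2 * score_one_handed(models, f1$obs_dom)$scores),
               tolerance = 1e-12)
  one <- two[1]
  expect_equal(score_two_handed(one, f1$obs_dom, f1$obs_dom)$class, 1L)
  expect_error(score_two_handed(two, f1$obs_dom, NULL), "both hands")
})

test_that("JSON serialization round-trips a fitted model bit-exactly", {
  ds <- small_dataset()
  seqs <- lapply(ds$features[ds$class_id == 2], function(f) f$obs_dom$O_A)
  fit <- hmm_fit(seqs, seed = 9)
  path <- tempfile(fileext = ".json")
  write_hmm_json(fit, path)
  back <- read_hmm_json(path)
  expect_identical(unclass(back)[c("pi", "A", "w", "means", "vars")],
                   lapply(unclass(fit)[c("pi", "A", "w", "means", "vars")],
                          unname))
  expect_identical(back$loglik_trace, fit$loglik_trace)
  unlink(path)
})
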