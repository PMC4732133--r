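# Independent brute-force oracles used to validate the fast
# implementations, plus small shared fixtures (built in code, memoized per
# test run).

# windowed average energy, literal double loop
naive_energy <- function(emg, window_len = 128L, step = 64L) {
  n <- nrow(emg)
  starts <- seq(1L, n - window_len + 1L, by = step)
  vapply(starts, function(s) {
    tot <- 0
    for (i in 1:4) {
      acc <- 0
      for (k in 0:(window_len - 1)) acc <- acc + abs(emg[s + k, i])^2
      tot <- tot + acc / window_len
    }
    tot / 4
  }, numeric(1))
}

naive_mav <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + abs(v)
  acc / length(x)
}

naive_var <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  acc / (length(x) - 1)
}

# predictor coefficients by direct solve of the Toeplitz normal equations
# (same biased autocorrelation as the Levinson-Durbin route)
lpc_toeplitz <- function(x, p) {
  n <- length(x)
  r <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n,
              numeric(1))
  phi <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
  -phi
}

# exhaustive-path forward probability of a Gaussian-mixture HMM
brute_loglik <- function(pi, A, w, means, vars, X) {
  S <- length(pi); T <- nrow(X)
  dens <- function(s, t) {
    sum(vapply(seq_len(ncol(w)), function(m)
      w[s, m] * prod(stats::dnorm(X[t, ], means[, m, s],
                                  sqrt(vars[, m, s]))),
      numeric(1)))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    q <- paths[r, ]
    p <- pi[q[1]] * dens(q[1], 1)
    if (T > 1) for (t in 2:T) p <- p * A[q[t - 1], q[t]] * dens(q[t], t)
    total <- total + p
  }
  log(total)
}

# random ergodic Gaussian-mixture HMM with moderate parameters
random_hmm <- function(S, M, D, seed) {
  set.seed(seed)
  rstoch <- function(n, k) {
    m <- matrix(stats::runif(n * k, 0.2, 1), n, k)
    m / rowSums(m)
  }
  list(pi = as.numeric(rstoch(1, S)), A = rstoch(S, S), w = rstoch(S, M),
       means = array(stats::rnorm(D * M * S), c(D, M, S)),
       vars = array(stats::runif(D * M * S, 0.3, 1.5), c(D, M, S)))
}

cont_hmm_from <- function(h) {
  structure(list(n_states = length(h$pi), n_mix = ncol(h$w),
                 dim = dim(h$means)[1], pi = h$pi, A = h$A, w = h$w,
                 means = h$means, vars = h$vars,
                 var_floor = rep(1e-8, dim(h$means)[1]),
                 loglik_trace = numeric(0)),
            class = "cont_hmm")
}

# sample sequences from a known HMM (for parameter-recovery checks)
simulate_hmm <- function(h, n_seq, len, seed) {
  set.seed(seed)
  S <- length(h$pi); M <- ncol(h$w); D <- dim(h$means)[1]
  lapply(seq_len(n_seq), function(i) {
    X <- matrix(0, len, D)
    s <- sample.int(S, 1, prob = h$pi)
    for (t in seq_len(len)) {
      if (t > 1) s <- sample.int(S, 1, prob = h$A[s, ])
      m <- sample.int(M, 1, prob = h$w[s, ])
      X[t, ] <- stats::rnorm(D, h$means[, m, s], sqrt(h$vars[, m, s]))
    }
    X
  })
}

# shared small labelled dataset (6 classes, 2 confusable pairs, mixed
# handedness); built once per test run
.fixtures <- new.env()
small_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    vocab <- make_vocabulary(6, n_confusable_pairs = 2,
                             frac_two_handed = 0.5, seed = 42)
    .fixtures$ds <- prepare_features(
      make_dataset(vocab, reps_per_class = 6, seed = 42))
  }
  .fixtures$ds
}

# one synthetic segment of a given handedness
one_segment <- function(two_handed = FALSE, seed = 5) {
  ds <- small_dataset()
  h <- vocab_handedness_of(ds)
  want <- if (two_handed) "two_handed" else "one_handed"
  i <- which(h[as.character(ds$class_id)] == want)[1]
  ds$segments[[i]]
}

vocab_pairs_of <- function(v) {
  out <- NULL
  for (s in v)
    if (!is.na(s$confusable_with) && s$class_id < s$confusable_with)
      out <- rbind(out, c(s$class_id, s$confusable_with))
  out
}

vocab_handedness_of <- function(ds) {
  h <- vapply(ds$vocab, function(s) s$handedness, character(1))
  names(h) <- vapply(ds$vocab, function(s) s$class_id, integer(1))
  h
}
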