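## Continuous Gaussian-mixture HMMs per observation stream, with
## Baum-Welch training (C++ core), scaled forward scoring, and the
## weighted multi-stream fusion rules used at the decision-tree leaves.

#' Fit a continuous Gaussian-mixture HMM by Baum-Welch
#'
#' Left-to-right topology (self-loops plus single-step forward
#' transitions, absorbing last state), diagonal-covariance Gaussian
#' mixture emissions.  Initialization is segmental: each training sequence
#' is split into `n_states` equal contiguous chunks, the pooled frames of
#' each state are clustered into `n_mix` components by k-means, and the EM
#' iterations then run until the total log-likelihood improves by less
#' than `tol` (relative) or `max_iter` is reached.  Variances are floored
#' at `1e-6` times the per-dimension training variance (with a small
#' absolute guard for degenerate dimensions), which keeps the constrained
#' EM monotone.
#'
#' @param sequences non-empty list of T x D numeric matrices; every T must
#'   be at least `n_states`.
#' @param n_states number of hidden states (default 5).
#' @param n_mix Gaussian mixture components per state (default 3).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood improvement threshold.
#' @param seed RNG seed for the k-means initialization.
#' @return an object of class `cont_hmm` with elements `pi`, `A`, `w`,
#'   `means`/`vars` (D x n_mix x n_states arrays), `var_floor` and
#'   `loglik_trace` (one total log-likelihood per EM iteration,
#'   non-decreasing).
#' @export
hmm_fit <- function(sequences, n_states = 5L, n_mix = 3L, max_iter = 20L,
                    tol = 1e-4, seed = 1L) {
  if (!is.list(sequences) || length(sequences) == 0)
    stop("at least one training sequence is required")
  sequences <- lapply(sequences, as.matrix)
  D <- ncol(sequences[[1]])
  if (any(vapply(sequences, ncol, integer(1)) != D))
    stop("sequences have inconsistent dimension")
  Ts <- vapply(sequences, nrow, integer(1))
  if (any(Ts < n_states))
    stop("every sequence must have at least n_states frames")

  allX <- do.call(rbind, sequences)
  var_floor <- pmax(1e-6 * apply(allX, 2, stats::var), 1e-8)

  # segmental initialization: state s gets the s-th time chunk of every
  # sequence
  pooled <- vector("list", n_states)
  for (x in sequences) {
    br <- round(seq(0, nrow(x), length.out = n_states + 1))
    for (s in seq_len(n_states)) {
      idx <- (br[s] + 1):br[s + 1]
      pooled[[s]] <- rbind(pooled[[s]], x[idx, , drop = FALSE])
    }
  }
  means <- array(0, c(D, n_mix, n_states))
  vars <- array(1, c(D, n_mix, n_states))
  w <- matrix(1 / n_mix, n_states, n_mix)
  for (s in seq_len(n_states)) {
    g <- init_state_gmm(pooled[[s]], n_mix, var_floor,
                        split_seed(seed, 7, s))
    means[, , s] <- g$means; vars[, , s] <- g$vars; w[s, ] <- g$w
  }

  Tbar <- mean(Ts)
  p_self <- min(0.95, max(0.3, 1 - n_states / Tbar))
  A <- diag(p_self, n_states)
  if (n_states > 1) {
    for (s in seq_len(n_states - 1)) A[s, s + 1] <- 1 - p_self
    A[n_states, n_states] <- 1
  } else A <- matrix(1, 1, 1)
  pi <- c(1, rep(0, n_states - 1))

  fit <- cpp_baum_welch(sequences, pi, A, w, means, vars,
                        as.integer(max_iter), tol, var_floor)
  structure(list(n_states = as.integer(n_states), n_mix = as.integer(n_mix),
                 dim = as.integer(D), pi = as.numeric(fit$pi), A = fit$A,
                 w = fit$w, means = array(fit$means, c(D, n_mix, n_states)),
                 vars = array(fit$vars, c(D, n_mix, n_states)),
                 var_floor = var_floor,
                 loglik_trace = as.numeric(fit$loglik_trace)),
            class = "cont_hmm")
}

# k-means GMM initialization of one state's pooled frames
init_state_gmm <- function(P, M, var_floor, seed) {
  D <- ncol(P)
  colvar <- function(x) pmax(apply(x, 2, stats::var), var_floor)
  if (M == 1 || nrow(unique(P)) < M) {
    mu0 <- colMeans(P)
    v0 <- if (nrow(P) > 1) colvar(P) else var_floor
    means <- matrix(rep(mu0, M), D, M)
    if (M > 1)  # break symmetry for duplicate centers
      means <- means + matrix(stats::rnorm(D * M, sd = sqrt(v0) / 10 + 1e-12),
                              D, M)
    return(list(means = means, vars = matrix(rep(v0, M), D, M),
                w = rep(1 / M, M)))
  }
  km <- local_seed(seed, suppressWarnings(
    stats::kmeans(P, centers = M, nstart = 2, iter.max = 20)))
  means <- t(km$centers)
  vars <- matrix(0, D, M)
  for (m in seq_len(M)) {
    Pm <- P[km$cluster == m, , drop = FALSE]
    vars[, m] <- if (nrow(Pm) > 1) colvar(Pm) else var_floor
  }
  w <- pmax(km$size / nrow(P), 0.05)
  list(means = means, vars = vars, w = w / sum(w))
}

#' @export
print.cont_hmm <- function(x, ...) {
  cat("Gaussian-mixture HMM:", x$n_states, "states,", x$n_mix,
      "mixture components, dim", x$dim, "\n")
  cat("  final log-likelihood:",
      x$loglik_trace[length(x$loglik_trace)], "after",
      length(x$loglik_trace), "EM iterations\n")
  invisible(x)
}

#' Forward-algorithm log-likelihood of a sequence
#'
#' `log P(sequence | model)` via the scaled forward recursion.
#'
#' @param model a `cont_hmm`.
#' @param sequence T x D numeric matrix with D matching the model.
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(model, sequence) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != model$dim)
    stop("sequence dimension does not match the model")
  cpp_forward_loglik(model$pi, model$A, model$w, model$means, model$vars,
                     sequence)
}

# per-stream score, optionally length-normalized so that the 64-frame ACC
# stream and the ~10-frame sEMG stream contribute on the same scale
stream_loglik <- function(model, X, normalize = TRUE) {
  ll <- hmm_loglik(model, X)
  if (normalize) ll / nrow(X) else ll
}

# fused score of one hand's observation pair against one class's two
# stream models (list with elements A and E)
hand_score <- function(ms, obs, delta_a, delta_e, normalize = TRUE) {
  delta_a * stream_loglik(ms$A, obs$O_A, normalize) +
    delta_e * stream_loglik(ms$E, obs$O_E, normalize)
}

check_deltas <- function(delta_a, delta_e) {
  if (delta_a < 0 || delta_e < 0 || abs(delta_a + delta_e - 1) > 1e-9)
    stop("stream weights must be non-negative and sum to 1")
}

#' Score a one-handed observation against per-class multi-stream HMMs
#'
#' Computes, for every candidate class, the weighted combination of the
#' per-stream forward log-likelihoods of the dominant hand,
#' `P_C = delta_A * logP(O_A | R_CA) + delta_E * logP(O_E | R_CE)`,
#' and returns the full score list together with the maximizing class
#' (ties broken toward the lowest class id).  Log-likelihoods are combined
#' in the log domain and, by default, normalized by frame count per
#' stream.
#'
#' @param models named list (names = class ids); each element a list with
#'   stream models `A` (ACC) and `E` (sEMG).
#' @param obs observation pair with `O_A` (64 x 3) and `O_E` (F x 20).
#' @param delta_a,delta_e non-negative stream weights summing to 1.
#' @param normalize divide each stream log-likelihood by its frame count.
#' @return list with `scores` (named numeric) and `class` (integer).
#' @export
score_one_handed <- function(models, obs, delta_a = 0.5, delta_e = 0.5,
                             normalize = TRUE) {
  check_deltas(delta_a, delta_e)
  if (length(models) == 0) stop("empty candidate set")
  scores <- vapply(models, hand_score, numeric(1), obs = obs,
                   delta_a = delta_a, delta_e = delta_e,
                   normalize = normalize)
  ids <- as.integer(names(models))
  best <- ids[order(-scores, ids)][1]
  list(scores = scores, class = best)
}

#' Score a two-handed observation against per-class multi-stream HMMs
#'
#' Each hand's score is formed as in [score_one_handed()]; the winning
#' class maximizes the combined (summed) likelihood of both hands.
#'
#' @param models named list per class with elements `R` and `L`, each a
#'   list of stream models `A` and `E`.
#' @param obs_r,obs_l observation pairs for the dominant and non-dominant
#'   hand.
#' @inheritParams score_one_handed
#' @return list with `scores` and `class`.
#' @export
score_two_handed <- function(models, obs_r, obs_l, delta_a = 0.5,
                             delta_e = 0.5, normalize = TRUE) {
  check_deltas(delta_a, delta_e)
  if (length(models) == 0) stop("empty candidate set")
  if (is.null(obs_l)) stop("two-handed scoring requires both hands")
  scores <- vapply(models, function(m) {
    hand_score(m$R, obs_r, delta_a, delta_e, normalize) +
      hand_score(m$L, obs_l, delta_a, delta_e, normalize)
  }, numeric(1))
  ids <- as.integer(names(models))
  best <- ids[order(-scores, ids)][1]
  list(scores = scores, class = best)
}

#' Serialize a Gaussian-mixture HMM to JSON
#'
#' All matrices are written row-major with explicit dimensions and full
#' double precision, so [read_hmm_json()] restores the model bit-exactly.
#'
#' @param model a `cont_hmm`.
#' @param path output file path.
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(
    type = "cont_hmm", n_states = model$n_states, n_mix = model$n_mix,
    dim = model$dim, pi = model$pi,
    A = list(dim = dim(model$A), data = as.numeric(t(model$A))),
    w = list(dim = dim(model$w), data = as.numeric(t(model$w))),
    means = list(dim = dim(model$means),
                 data = as.numeric(aperm(model$means, c(3, 2, 1)))),
    vars = list(dim = dim(model$vars),
                data = as.numeric(aperm(model$vars, c(3, 2, 1)))),
    var_floor = model$var_floor, loglik_trace = model$loglik_trace)
  # I(17) significant digits uniquely identify every double, making the
  # round-trip bit-exact
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a Gaussian-mixture HMM from JSON
#'
#' @param path file written by [write_hmm_json()].
#' @return a `cont_hmm`.
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "cont_hmm")) stop("not a cont_hmm JSON file")
  unflat <- function(x) aperm(array(x$data, rev(x$dim)),
                              rev(seq_along(x$dim)))
  structure(list(n_states = as.integer(obj$n_states),
                 n_mix = as.integer(obj$n_mix), dim = as.integer(obj$dim),
                 pi = as.numeric(obj$pi), A = unflat(obj$A),
                 w = unflat(obj$w), means = unflat(obj$means),
                 vars = unflat(obj$vars),
                 var_floor = as.numeric(obj$var_floor),
                 loglik_trace = as.numeric(obj$loglik_trace)),
            class = "cont_hmm")
}
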