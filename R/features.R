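## Per-segment features: time-domain statistics, linear prediction
## coefficients, and the stage-specific feature vectors and HMM observation
## sequences consumed by the classifiers.

#' Mean absolute value of a signal segment
#'
#' `MAV = (1/N) * sum |x(n)|`, an amplitude/energy descriptor.
#'
#' @param x non-empty numeric vector.
#' @return non-negative scalar.
#' @export
mav <- function(x) {
  if (length(x) == 0) stop("empty input")
  mean(abs(x))
}

#' Linear prediction coefficients by the autocorrelation method
#'
#' Fits the all-pole predictor `x(n) ~ -sum_{k=1..p} l_k x(n-k)` using the
#' biased sample autocorrelation and the Levinson-Durbin recursion.  Under
#' this sign convention the returned coefficients equal the `a_k` of the
#' equivalent AR-plus-white-noise model `x(n) = w(n) - sum a_k x(n-k)`; one
#' routine serves both uses.
#'
#' Constant (zero-variance) input returns the defined fallback of all-zero
#' coefficients.
#'
#' @param x numeric vector with `length(x) > p`.
#' @param p predictor order (>= 1).
#' @return numeric vector of `p` coefficients.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::filter(rnorm(5000), 0.5, method = "recursive"))
#' lpc(x, 1)  # close to -(-0.5) = -0.5 ... sign per the AR convention
lpc <- function(x, p = 4L) {
  n <- length(x)
  if (p < 1) stop("order p must be >= 1")
  if (n <= p) stop("signal must be longer than the order")
  x <- as.numeric(x)
  if (max(x) == min(x)) return(numeric(p))  # constant input fallback
  r <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n,
              numeric(1))
  if (!is.finite(r[1]) || r[1] <= 0) return(numeric(p))
  phi <- numeric(p)  # forward predictor: x(n) ~ sum phi_k x(n-k)
  e <- r[1]
  for (m in 1:p) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(phi[1:(m - 1)] * r[m:2])
    if (e <= 0) { k <- 0 } else { k <- acc / e }
    new <- phi
    new[m] <- k
    if (m > 1) new[1:(m - 1)] <- phi[1:(m - 1)] - k * phi[(m - 1):1]
    phi <- new
    e <- e * (1 - k^2)
  }
  -phi
}

# channel layouts
DOM_EMG <- 1:4; NDOM_EMG <- 5:8
DOM_ACC <- 1:3; NDOM_ACC <- 4:6

check_segment <- function(segment) {
  if (!is.matrix(segment$emg) || ncol(segment$emg) != 8 ||
      !is.matrix(segment$acc) || ncol(segment$acc) != 6)
    stop("malformed segment: expected 8 sEMG and 6 ACC channels")
  if (nrow(segment$emg) != nrow(segment$acc))
    stop("malformed segment: channel lengths differ")
}

#' 42-dimensional pre-classifier feature vector
#'
#' For each of the 7 dominant-hand channels (4 sEMG + 3 ACC axes), in
#' channel-major order: MAV, unbiased variance, and the 4 LPC
#' coefficients.
#'
#' @param segment a `subword_segment`.
#' @return numeric vector of length 42.
#' @export
build_preclassifier_vector <- function(segment) {
  check_segment(segment)
  if (nrow(segment$emg) < 5) stop("segment too short")
  chans <- cbind(segment$emg[, DOM_EMG, drop = FALSE],
                 segment$acc[, DOM_ACC, drop = FALSE])
  v <- as.numeric(apply(chans, 2, function(x) {
    c(mav(x), stats::var(x), lpc(x, 4L))
  }))
  names(v) <- as.vector(outer(c("mav", "var", paste0("lpc", 1:4)),
                              colnames(chans),
                              function(f, ch) paste(ch, f, sep = ".")))
  v
}

#' 10-dimensional one-/two-handed feature vector
#'
#' Non-dominant forearm only: MAV of the 4 sEMG channels, then mean and
#' standard deviation of each of the 3 ACC axes.
#'
#' @param segment a `subword_segment`.
#' @return numeric vector of length 10.
#' @export
build_handedness_vector <- function(segment) {
  check_segment(segment)
  if (nrow(segment$emg) < 5) stop("segment too short")
  e <- segment$emg[, NDOM_EMG, drop = FALSE]
  a <- segment$acc[, NDOM_ACC, drop = FALSE]
  v <- c(apply(e, 2, mav), colMeans(a), apply(a, 2, stats::sd))
  names(v) <- c(paste0(colnames(e), ".mav"),
                paste0(colnames(a), ".mean"), paste0(colnames(a), ".sd"))
  v
}

#' 3-dimensional hand-orientation feature vector
#'
#' Mean of each dominant-hand ACC axis over the segment; at rest the ACC
#' measures the gravity projection, so these means encode hand
#' orientation.
#'
#' @param segment a `subword_segment`.
#' @return numeric vector of length 3.
#' @export
build_orientation_vector <- function(segment) {
  check_segment(segment)
  colMeans(segment$acc[, DOM_ACC, drop = FALSE])
}

#' Two-stream HMM observation for one hand
#'
#' `O_A`: each of the hand's 3 ACC axes linearly interpolated onto 64
#' equally spaced points spanning the segment (inclusive endpoints), which
#' normalizes movement duration.  `O_E`: the hand's 4 sEMG channels framed
#' with a 128-sample window and 64-sample step; each frame contributes, per
#' channel, its MAV followed by 4 LPC coefficients (20 values per frame,
#' channel-major).  A trailing partial frame is discarded, so a segment of
#' length `L >= 128` yields `floor((L - 128)/64) + 1` frames.
#'
#' @param segment a `subword_segment` of at least 128 samples.
#' @param hand `"dominant"` or `"nondominant"`.
#' @return list with `O_A` (64 x 3) and `O_E` (F x 20).
#' @export
build_observations <- function(segment, hand = c("dominant", "nondominant")) {
  hand <- match.arg(hand)
  check_segment(segment)
  L <- nrow(segment$emg)
  if (L < 128) stop("segment shorter than one frame (128 samples)")
  eidx <- if (hand == "dominant") DOM_EMG else NDOM_EMG
  aidx <- if (hand == "dominant") DOM_ACC else NDOM_ACC

  acc <- segment$acc[, aidx, drop = FALSE]
  O_A <- apply(acc, 2, function(x)
    stats::approx(seq_len(L), x, n = 64)$y)

  emg <- segment$emg[, eidx, drop = FALSE]
  starts <- seq(1L, L - 128L + 1L, by = 64L)
  O_E <- t(vapply(starts, function(s) {
    fr <- emg[s:(s + 127L), , drop = FALSE]
    as.numeric(apply(fr, 2, function(x) c(mav(x), lpc(x, 4L))))
  }, numeric(20)))
  list(O_A = O_A, O_E = O_E)
}

# All per-segment features needed by the decision tree, computed once.
segment_features <- function(segment) {
  list(pre = build_preclassifier_vector(segment),
       hand10 = build_handedness_vector(segment),
       orient = build_orientation_vector(segment),
       obs_dom = build_observations(segment, "dominant"),
       obs_ndom = build_observations(segment, "nondominant"))
}

#' Precompute classifier features for every segment of a dataset
#'
#' Feature extraction is by far the most expensive per-segment step, so
#' training functions cache it on the dataset; calling this explicitly lets
#' one dataset be reused across many trees, folds and experiments.
#'
#' @param dataset an `slr_dataset`.
#' @return the dataset with a `features` element filled in.
#' @export
prepare_features <- function(dataset) {
  if (!is.null(dataset$features)) return(dataset)
  dataset$features <- lapply(dataset$segments, segment_features)
  dataset
}
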