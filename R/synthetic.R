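## Synthetic sEMG + ACC subword generator.
##
## Emulates two instrumented forearms: per hand, 4 surface-EMG channels and
## one tri-axial accelerometer, sampled at 1 kHz.  A subword is a burst of
## amplitude-modulated AR(4)-colored noise on the active sEMG channels,
## while each ACC channel sits on a gravity baseline set by the hand
## orientation plus a smooth motion-trajectory component.  One-handed
## subwords leave the non-dominant (left) channels at the noise floor.

FS_HZ <- 1000L

#' Candidate hand-orientation gravity directions
#'
#' Eight unit vectors (the six axis directions plus two diagonals) used as
#' the discrete set of resting hand orientations.  A subword's
#' `orientation_id` (0-based) indexes a row.
#'
#' @return an 8 x 3 numeric matrix of unit vectors.
#' @export
orientation_vectors <- function() {
  d <- 1 / sqrt(3)
  m <- rbind(
    c( 1, 0, 0), c(-1, 0, 0),
    c( 0, 1, 0), c( 0,-1, 0),
    c( 0, 0, 1), c( 0, 0,-1),
    c( d, d, d), c(-d, d,-d))
  rownames(m) <- paste0("orient", 0:7)
  colnames(m) <- c("x", "y", "z")
  m
}

# orientation id used for a resting (non-dominant, one-handed) hand: +z
REST_ORIENTATION <- 4L

emg_channel_names <- function() c(paste0("emgR", 1:4), paste0("emgL", 1:4))
acc_channel_names <- function() c("accRx", "accRy", "accRz",
                                  "accLx", "accLy", "accLz")

#' Construct a subword specification
#'
#' A `subword_spec` fixes every deterministic property of a subword class:
#' its handedness, its hand orientation (gravity direction per hand), the
#' per-channel sEMG activation envelopes and AR(4) noise-shaping filters,
#' the per-axis ACC motion trajectories, and the nominal duration.
#' Repetitions of the class re-synthesize the same spec under independent
#' noise and a small execution-to-execution jitter.
#'
#' @param class_id integer class label.
#' @param handedness `"one_handed"` or `"two_handed"`.
#' @param orientation_id dominant-hand orientation, integer in 0..7.
#' @param orientation_id_nd non-dominant-hand orientation (0..7); for
#'   one-handed specs this is the rest orientation.
#' @param gains numeric(8), peak envelope gain per sEMG channel (dominant
#'   channels 1-4, non-dominant 5-8); 0 marks an inactive channel.
#' @param bumps list of 8 matrices with columns `center`, `width`, `height`
#'   (fractions of the subword duration) describing raised-cosine activation
#'   bumps per channel.
#' @param ar 8 x 4 matrix of AR coefficients `a_k` per channel under the
#'   convention `x(n) = w(n) - sum_k a_k x(n-k)`; each row must define a
#'   stable all-pole filter.
#' @param traj 6 x 3 matrix (rows accRx..accLz) of trajectory parameters
#'   `amp`, `freq` (cycles per subword), `phase`.
#' @param duration_ms nominal subword duration, >= 640 ms so a segment
#'   yields at least 9 energy windows.
#' @param env_floor sustained activation level between bumps, in (0, 1];
#'   keeps the mid-subword energy above the segmentation threshold.
#' @param confusable_with optional class_id of a confusable partner.
#' @return an object of class `subword_spec`.
#' @export
subword_spec <- function(class_id, handedness, orientation_id,
                         orientation_id_nd = REST_ORIENTATION,
                         gains, bumps, ar, traj, duration_ms,
                         env_floor = 0.8, confusable_with = NA_integer_) {
  stopifnot(handedness %in% c("one_handed", "two_handed"),
            orientation_id %in% 0:7, orientation_id_nd %in% 0:7,
            length(gains) == 8, is.list(bumps), length(bumps) == 8,
            is.matrix(ar), all(dim(ar) == c(8, 4)),
            is.matrix(traj), all(dim(traj) == c(6, 3)),
            duration_ms >= 640, env_floor > 0, env_floor <= 1)
  for (c in 1:8) {
    if (gains[c] > 0 && !ar_stable(ar[c, ]))
      stop("ar row ", c, " is not a stable all-pole filter")
  }
  if (handedness == "one_handed") {
    if (any(gains[5:8] != 0) || any(traj[4:6, 1] != 0))
      stop("one-handed specs must have quiet non-dominant channels")
  }
  structure(list(class_id = as.integer(class_id), handedness = handedness,
                 orientation_id = as.integer(orientation_id),
                 orientation_id_nd = as.integer(orientation_id_nd),
                 gains = as.numeric(gains), bumps = bumps, ar = ar,
                 traj = traj, duration_ms = as.numeric(duration_ms),
                 env_floor = env_floor,
                 confusable_with = as.integer(confusable_with)),
            class = "subword_spec")
}

# TRUE when all poles of 1 + a1 z^-1 + ... + a4 z^-4 lie inside the unit
# circle, i.e. z^4 + a1 z^3 + a2 z^2 + a3 z + a4 has all roots with |z| < 1.
ar_stable <- function(a) {
  all(Mod(polyroot(c(rev(a), 1))) < 1)
}

# Random stable AR(4): two conjugate pole pairs with moderate radii.
random_ar4 <- function() {
  r <- stats::runif(2, 0.4, 0.85)
  th <- stats::runif(2, 0.15 * pi, 0.85 * pi)
  q1 <- c(1, -2 * r[1] * cos(th[1]), r[1]^2)
  q2 <- c(1, -2 * r[2] * cos(th[2]), r[2]^2)
  # convolution gives A(z) = 1 + a1 z^-1 + ... + a4 z^-4
  a <- stats::convolve(q1, rev(q2), type = "open")[2:5]
  a
}

random_bumps <- function(n_bumps) {
  cbind(center = sort(stats::runif(n_bumps, 0.15, 0.85)),
        width  = stats::runif(n_bumps, 0.15, 0.35),
        height = stats::runif(n_bumps, 0.5, 1))
}

random_traj_row <- function() {
  c(amp = stats::runif(1, 0.15, 0.45), freq = sample(1:2, 1),
    phase = stats::runif(1, 0, 2 * pi))
}

zero_bumps <- function() cbind(center = 0.5, width = 0.3, height = 0)

#' Generate a vocabulary of subword classes
#'
#' Draws `n_classes` subword specifications.  `n_confusable_pairs` of them
#' are built as pairs in which the second member is a small perturbation of
#' the first (envelope timing and trajectory amplitude only; handedness,
#' orientation and AR shaping are shared), emulating sign pairs with nearly
#' identical execution.  Orientations are drawn from the 8 candidate
#' gravity directions and handedness is assigned to match
#' `frac_two_handed` as closely as the pair structure allows (pair members
#' always share handedness).
#'
#' @param n_classes number of classes (>= 2).
#' @param n_confusable_pairs number of linked pairs; `2 * n_confusable_pairs
#'   <= n_classes`.
#' @param frac_two_handed target proportion of two-handed classes in [0, 1].
#' @param seed RNG seed; the vocabulary is deterministic given the seed.
#' @param perturb_scale relative size of the within-pair perturbation
#'   (default 0.25).  Larger values make pairs easier to separate.
#' @return a list of [subword_spec()] objects of class `slr_vocab`.
#' @export
#' @examples
#' vocab <- make_vocabulary(6, n_confusable_pairs = 2, seed = 1)
#' sapply(vocab, function(s) s$handedness)
make_vocabulary <- function(n_classes, n_confusable_pairs = 0,
                            frac_two_handed = 0.5, seed = 1,
                            perturb_scale = 0.25) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (frac_two_handed < 0 || frac_two_handed > 1)
    stop("frac_two_handed must lie in [0, 1]")
  if (2 * n_confusable_pairs > n_classes)
    stop("2 * n_confusable_pairs must not exceed n_classes")
  local_seed(split_seed(seed, 90001), {
    perm <- sample(n_classes)
    pair_first  <- if (n_confusable_pairs > 0)
      perm[seq(1, 2 * n_confusable_pairs, by = 2)] else integer(0)
    pair_second <- if (n_confusable_pairs > 0)
      perm[seq(2, 2 * n_confusable_pairs, by = 2)] else integer(0)
    singles <- if (2 * n_confusable_pairs < n_classes)
      perm[(2 * n_confusable_pairs + 1):n_classes] else integer(0)

    # assign handedness per unit (pair or singleton) to hit the target count
    target <- round(frac_two_handed * n_classes)
    units <- c(lapply(seq_along(pair_first),
                      function(i) c(pair_first[i], pair_second[i])),
               as.list(singles))
    units <- units[sample(length(units))]
    two_handed <- rep(FALSE, n_classes)
    left <- target
    for (u in units[order(-lengths(units))]) {
      if (left >= length(u)) { two_handed[u] <- TRUE; left <- left - length(u) }
    }

    specs <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      if (i %in% pair_second) next  # built from its partner below
      th <- two_handed[i]
      hand <- if (th) "two_handed" else "one_handed"
      gains <- c(stats::runif(4, 2.2, 3.0),
                 if (th) stats::runif(4, 2.2, 3.0) else rep(0, 4))
      bumps <- lapply(1:8, function(c) {
        if (gains[c] > 0) random_bumps(sample(1:3, 1)) else zero_bumps()
      })
      ar <- t(vapply(1:8, function(c) random_ar4(), numeric(4)))
      traj <- rbind(t(vapply(1:3, function(k) random_traj_row(), numeric(3))),
                    if (th) t(vapply(1:3, function(k) random_traj_row(),
                                     numeric(3)))
                    else matrix(0, 3, 3))
      dimnames(traj) <- list(acc_channel_names(),
                             c("amp", "freq", "phase"))
      specs[[i]] <- subword_spec(
        class_id = i, handedness = hand,
        orientation_id = sample(0:7, 1),
        orientation_id_nd = if (th) sample(0:7, 1) else REST_ORIENTATION,
        gains = gains, bumps = bumps, ar = ar, traj = traj,
        duration_ms = stats::runif(1, 800, 1100))
    }
    # confusable partners: same class structure, perturbed envelope timing
    # and trajectory amplitude only
    for (j in seq_along(pair_second)) {
      base <- specs[[pair_first[j]]]
      pb <- base
      pb$class_id <- as.integer(pair_second[j])
      pb$bumps <- lapply(pb$bumps, function(b) {
        b[, "center"] <- pmin(0.9, pmax(0.1,
          b[, "center"] + perturb_scale * 0.3 *
            stats::runif(nrow(b), -1, 1)))
        b
      })
      pb$traj[, "amp"] <- pb$traj[, "amp"] *
        (1 + perturb_scale * sign(stats::runif(6, -1, 1)) * 0.8)
      pb$confusable_with <- as.integer(pair_first[j])
      specs[[pair_second[j]]] <- do.call(subword_spec, pb)
      specs[[pair_first[j]]]$confusable_with <- as.integer(pair_second[j])
    }
    structure(specs, class = "slr_vocab")
  })
}

#' @export
print.slr_vocab <- function(x, ...) {
  hp <- sum(vapply(x, function(s) s$handedness == "two_handed", logical(1)))
  np <- sum(vapply(x, function(s) !is.na(s$confusable_with), logical(1))) / 2
  cat("Subword vocabulary:", length(x), "classes (", hp, "two-handed,",
      np, "confusable pairs )\n")
  invisible(x)
}

# Unit-variance AR(4)-colored Gaussian noise (Eq.-(3) sign convention).
colored_noise <- function(n, a, burn = 500L) {
  w <- stats::rnorm(n + burn)
  x <- stats::filter(w, -a, method = "recursive")
  x <- as.numeric(x)[(burn + 1):(burn + n)]
  x / stats::sd(x)
}

# Raised-cosine bump profile on u in [0, 1].
bump_profile <- function(u, bumps) {
  b <- numeric(length(u))
  for (j in seq_len(nrow(bumps))) {
    d <- abs(u - bumps[j, "center"]) / bumps[j, "width"]
    inside <- d < 1
    b[inside] <- b[inside] +
      bumps[j, "height"] * 0.5 * (1 + cos(pi * d[inside]))
  }
  b
}

# Activation envelope over an active region of n samples: edge taper times
# (floor + (1 - floor) * normalized bumps).
activation_envelope <- function(n, bumps, env_floor, taper_ms = 64) {
  u <- seq(0, 1, length.out = n)
  tp <- rep(1, n)
  k <- min(round(taper_ms * FS_HZ / 1000), floor(n / 2))
  if (k > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(k) / k))
    tp[1:k] <- ramp
    tp[(n - k + 1):n] <- rev(ramp)
  }
  b <- bump_profile(u, bumps)
  mb <- max(b)
  base <- if (mb > 0) env_floor + (1 - env_floor) * b / mb else rep(env_floor, n)
  tp * base
}

# Synthesize the active region of one subword: emg (n x 8) and acc (n x 6)
# including in-band baseline noise, plus realized duration.  Jitter emulates
# execution-to-execution variability.
synth_active <- function(spec, seed, noise_floor, g_scale, acc_noise,
                         jitter) {
  local_seed(seed, {
    dmul <- 1 + stats::runif(1, -1, 1) * 0.3 * jitter
    n <- max(640L, as.integer(round(spec$duration_ms * dmul)))
    gmul <- exp(stats::runif(8, -1, 1) * 0.3 * jitter)
    amul <- exp(stats::runif(6, -1, 1) * 0.5 * jitter)
    csh  <- stats::runif(8, -1, 1) * 0.15 * jitter

    emg <- matrix(0, n, 8, dimnames = list(NULL, emg_channel_names()))
    for (c in 1:8) {
      g <- spec$gains[c] * gmul[c]
      if (g > 0) {
        b <- spec$bumps[[c]]
        b[, "center"] <- pmin(0.95, pmax(0.05, b[, "center"] + csh[c]))
        env <- g * activation_envelope(n, b, spec$env_floor)
        emg[, c] <- env * colored_noise(n, spec$ar[c, ])
      }
      emg[, c] <- emg[, c] + noise_floor * stats::rnorm(n)
    }

    ov <- orientation_vectors()
    grav <- c(g_scale * ov[spec$orientation_id + 1L, ],
              g_scale * ov[spec$orientation_id_nd + 1L, ])
    u <- seq(0, 1, length.out = n)
    win <- sin(pi * u)^2
    acc <- matrix(0, n, 6, dimnames = list(NULL, acc_channel_names()))
    for (k in 1:6) {
      tr <- spec$traj[k, "amp"] * amul[k] *
        sin(2 * pi * spec$traj[k, "freq"] * u + spec$traj[k, "phase"]) * win
      acc[, k] <- grav[k] + tr + acc_noise * stats::rnorm(n)
    }
    list(emg = emg, acc = acc, n = n)
  })
}

new_recording <- function(emg, acc, annotations, fs_hz = FS_HZ) {
  stopifnot(nrow(emg) == nrow(acc), ncol(emg) == 8, ncol(acc) == 6)
  structure(list(fs_hz = as.integer(fs_hz), emg = emg, acc = acc,
                 annotations = annotations),
            class = "slr_recording")
}

#' @export
print.slr_recording <- function(x, ...) {
  cat("sEMG+ACC recording:", nrow(x$emg), "samples @", x$fs_hz, "Hz,",
      nrow(x$annotations), "annotated subword(s)\n")
  invisible(x)
}

# baseline-only stretch of a recording
baseline_block <- function(n, spec_grav, noise_floor, g_scale, acc_noise,
                           seed) {
  local_seed(seed, {
    emg <- matrix(noise_floor * stats::rnorm(n * 8), n, 8,
                  dimnames = list(NULL, emg_channel_names()))
    acc <- matrix(stats::rnorm(n * 6, sd = acc_noise), n, 6,
                  dimnames = list(NULL, acc_channel_names()))
    acc <- sweep(acc, 2, spec_grav, "+")
    list(emg = emg, acc = acc)
  })
}

#' Synthesize one isolated subword recording
#'
#' Produces a continuous recording containing a single execution of `spec`,
#' padded with baseline (rest) signal on both sides.  The annotation marks
#' the active region with 0-based inclusive sample indices.
#'
#' @param spec a [subword_spec()].
#' @param seed RNG seed; output is deterministic given `(spec, seed)`.
#' @param noise_floor standard deviation of the sEMG baseline noise.
#' @param g_scale magnitude of the gravity component on the ACC channels.
#' @param acc_noise standard deviation of the ACC sensor noise.
#' @param jitter relative execution-to-execution variability (0 disables).
#' @param pad_ms baseline padding before and after the subword.
#' @return an `slr_recording`.
#' @export
synthesize_subword <- function(spec, seed, noise_floor = 0.05, g_scale = 1,
                               acc_noise = 0.03, jitter = 0.1,
                               pad_ms = 320) {
  core <- synth_active(spec, split_seed(seed, 1), noise_floor, g_scale,
                       acc_noise, jitter)
  np <- as.integer(round(pad_ms * FS_HZ / 1000))
  ov <- orientation_vectors()
  grav <- c(g_scale * ov[spec$orientation_id + 1L, ],
            g_scale * ov[spec$orientation_id_nd + 1L, ])
  pre  <- baseline_block(np, grav, noise_floor, g_scale, acc_noise,
                         split_seed(seed, 2))
  post <- baseline_block(np, grav, noise_floor, g_scale, acc_noise,
                         split_seed(seed, 3))
  emg <- rbind(pre$emg, core$emg, post$emg)
  acc <- rbind(pre$acc, core$acc, post$acc)
  ann <- data.frame(class_id = spec$class_id, t_start = np,
                    t_end = np + core$n - 1L)
  new_recording(emg, acc, ann)
}

#' Synthesize a sentence of concatenated subwords
#'
#' Concatenates the active regions of the given specs, separated (and
#' flanked) by low-activity gaps that emulate movement epenthesis between
#' subwords.  Ground-truth boundaries of every subword are annotated.
#'
#' @param specs ordered list of [subword_spec()] objects.
#' @param gap_ms gap duration between subwords, >= 256 ms so the
#'   below-threshold run between segments spans at least two energy windows.
#' @inheritParams synthesize_subword
#' @return an `slr_recording` with one annotation per subword.
#' @export
synthesize_sentence <- function(specs, gap_ms = 500, seed = 1,
                                noise_floor = 0.05, g_scale = 1,
                                acc_noise = 0.03, jitter = 0.1) {
  if (length(specs) == 0) stop("specs must contain at least one subword")
  if (gap_ms < 256) stop("gap_ms must be >= 256")
  ng <- as.integer(round(gap_ms * FS_HZ / 1000))
  ov <- orientation_vectors()
  rest_grav <- c(g_scale * ov[REST_ORIENTATION + 1L, ],
                 g_scale * ov[REST_ORIENTATION + 1L, ])
  emg <- list(); acc <- list(); ann <- NULL; pos <- 0L
  for (i in seq_along(specs)) {
    gap <- baseline_block(ng, rest_grav, noise_floor, g_scale, acc_noise,
                          split_seed(seed, 10000 + i))
    emg[[length(emg) + 1L]] <- gap$emg
    acc[[length(acc) + 1L]] <- gap$acc
    pos <- pos + ng
    core <- synth_active(specs[[i]], split_seed(seed, i), noise_floor,
                         g_scale, acc_noise, jitter)
    emg[[length(emg) + 1L]] <- core$emg
    acc[[length(acc) + 1L]] <- core$acc
    ann <- rbind(ann, data.frame(class_id = specs[[i]]$class_id,
                                 t_start = pos, t_end = pos + core$n - 1L))
    pos <- pos + core$n
  }
  tail_gap <- baseline_block(ng, rest_grav, noise_floor, g_scale, acc_noise,
                             split_seed(seed, 10000 + length(specs) + 1L))
  emg[[length(emg) + 1L]] <- tail_gap$emg
  acc[[length(acc) + 1L]] <- tail_gap$acc
  new_recording(do.call(rbind, emg), do.call(rbind, acc), ann)
}

#' Synthesize a maximal-voluntary-contraction recording
#'
#' All four dominant-hand sEMG channels are driven at the maximal envelope
#' gain for the whole duration.  The mean windowed energy of this recording
#' calibrates the segmentation threshold (see [calibrate_threshold()]).
#'
#' @param seed RNG seed.
#' @param duration_ms contraction duration.
#' @param mvc_gain envelope gain of the contraction (the top of the range
#'   used for subword channels).
#' @param noise_floor sEMG baseline noise standard deviation.
#' @return an `slr_recording` with no padding.
#' @export
synthesize_mvc <- function(seed = 1, duration_ms = 2000, mvc_gain = 3,
                           noise_floor = 0.05) {
  ar <- local_seed(split_seed(seed, 77), {
    t(vapply(1:8, function(c) random_ar4(), numeric(4)))
  })
  spec <- subword_spec(
    class_id = 0L, handedness = "one_handed", orientation_id = REST_ORIENTATION,
    gains = c(rep(mvc_gain, 4), rep(0, 4)),
    bumps = c(replicate(4, zero_bumps(), simplify = FALSE),
              replicate(4, zero_bumps(), simplify = FALSE)),
    ar = ar, traj = matrix(0, 6, 3,
                           dimnames = list(acc_channel_names(),
                                           c("amp", "freq", "phase"))),
    duration_ms = duration_ms, env_floor = 1)
  core <- synth_active(spec, split_seed(seed, 1), noise_floor, 1, 0.03,
                       jitter = 0)
  new_recording(core$emg, core$acc,
                data.frame(class_id = 0L, t_start = 0L,
                           t_end = core$n - 1L))
}

#' Excise the annotated subword segments of a recording
#'
#' @param recording an annotated `slr_recording`.
#' @return a list of `subword_segment` objects (all 14 channels sliced to
#'   the annotated span, labelled with the annotation's class).
#' @export
extract_annotated_segments <- function(recording) {
  ann <- recording$annotations
  lapply(seq_len(nrow(ann)), function(i) {
    idx <- (ann$t_start[i] + 1L):(ann$t_end[i] + 1L)
    new_segment(recording$emg[idx, , drop = FALSE],
                recording$acc[idx, , drop = FALSE],
                class_id = ann$class_id[i],
                sample_start = ann$t_start[i], sample_end = ann$t_end[i],
                fs_hz = recording$fs_hz)
  })
}

new_segment <- function(emg, acc, class_id = NA_integer_,
                        sample_start = NA_integer_, sample_end = NA_integer_,
                        fs_hz = FS_HZ) {
  structure(list(emg = emg, acc = acc, class_id = as.integer(class_id),
                 sample_start = sample_start, sample_end = sample_end,
                 fs_hz = fs_hz),
            class = "subword_segment")
}

#' @export
print.subword_segment <- function(x, ...) {
  cat("Subword segment:", nrow(x$emg), "samples",
      if (!is.na(x$class_id)) paste0("(class ", x$class_id, ")"), "\n")
  invisible(x)
}

#' Generate a labelled dataset of isolated subword segments
#'
#' Synthesizes `reps_per_class` independent executions of every class in
#' the vocabulary and excises them to segments using the generator's ground
#' truth boundaries.  Samples are tagged with a repetition index (1..3 by
#' default) so the dataset plugs directly into three-fold cross-validation
#' by repetition.
#'
#' @param vocab an `slr_vocab` from [make_vocabulary()].
#' @param reps_per_class executions per class (>= 1).
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @param n_repetitions number of repetition groups for cross-validation.
#' @inheritParams synthesize_subword
#' @return an `slr_dataset`: list with `segments`, `class_id`,
#'   `repetition`, `vocab` and the generator parameters.
#' @export
#' @examples
#' vocab <- make_vocabulary(3, seed = 1)
#' ds <- make_dataset(vocab, reps_per_class = 3, seed = 1)
#' table(ds$class_id)
make_dataset <- function(vocab, reps_per_class = 12, seed = 1,
                         n_repetitions = 3, noise_floor = 0.05,
                         g_scale = 1, acc_noise = 0.03, jitter = 0.1) {
  stopifnot(reps_per_class >= 1)
  segments <- list(); class_id <- integer(0); repetition <- integer(0)
  for (i in seq_along(vocab)) {
    for (j in seq_len(reps_per_class)) {
      rec <- synthesize_subword(vocab[[i]], split_seed(seed, i, j),
                                noise_floor = noise_floor,
                                g_scale = g_scale, acc_noise = acc_noise,
                                jitter = jitter)
      seg <- extract_annotated_segments(rec)[[1]]
      segments[[length(segments) + 1L]] <- seg
      class_id <- c(class_id, vocab[[i]]$class_id)
      repetition <- c(repetition, ((j - 1L) %% n_repetitions) + 1L)
    }
  }
  structure(list(segments = segments, class_id = class_id,
                 repetition = repetition, vocab = vocab,
                 params = list(seed = seed, noise_floor = noise_floor,
                               g_scale = g_scale, acc_noise = acc_noise,
                               jitter = jitter,
                               reps_per_class = reps_per_class)),
            class = "slr_dataset")
}

#' @export
print.slr_dataset <- function(x, ...) {
  cat("Subword dataset:", length(x$segments), "segments,",
      length(unique(x$class_id)), "classes,",
      max(x$repetition), "repetition groups\n")
  invisible(x)
}

# class -> handedness lookup from a vocabulary
vocab_handedness <- function(vocab) {
  h <- vapply(vocab, function(s) s$handedness, character(1))
  names(h) <- vapply(vocab, function(s) s$class_id, integer(1))
  h
}

# declared confusable pairs (each once, first id < second id)
vocab_pairs <- function(vocab) {
  out <- NULL
  for (s in vocab) {
    if (!is.na(s$confusable_with) && s$class_id < s$confusable_with)
      out <- rbind(out, c(s$class_id, s$confusable_with))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}
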