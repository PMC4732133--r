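## Energy-based subword segmentation of continuous recordings.
##
## The dominant hand participates in every subword, so its four sEMG
## channels drive boundary detection: short-time average energy is compared
## against a threshold calibrated from the signer's maximal voluntary
## contraction, and two five-window onset/offset patterns mark segment
## boundaries, which are then enforced on all 14 channels.

#' Short-time average energy of the dominant-hand sEMG channels
#'
#' Divides the four dominant-hand sEMG channels into sliding windows
#' (default 128 samples, step 64) and computes, per window,
#' `E_W(t) = (1/4) * sum_i (1/N) * sum_n x_i[n]^2`, the per-channel mean
#' square power averaged over channels.  A trailing partial window is
#' discarded.
#'
#' @param emg_dominant numeric matrix, T samples x 4 channels.
#' @param window_len window length in samples.
#' @param step window increment in samples.
#' @return an `energy_series`: list with `values`, `window_len`, `step`,
#'   `t0` (sample index of the first window start, 0-based).
#' @export
#' @examples
#' e <- average_energy(matrix(1:4, nrow = 256, ncol = 4, byrow = TRUE))
#' e$values[1]  # (1 + 4 + 9 + 16) / 4
average_energy <- function(emg_dominant, window_len = 128L, step = 64L) {
  emg_dominant <- as.matrix(emg_dominant)
  if (ncol(emg_dominant) != 4)
    stop("exactly 4 dominant-hand sEMG channels are required")
  n <- nrow(emg_dominant)
  if (n < window_len) stop("window_len exceeds the signal length")
  starts <- seq(1L, n - window_len + 1L, by = step)
  sq <- emg_dominant^2
  # cumulative sums give each window's sum in O(1)
  cs <- rbind(0, apply(sq, 2, cumsum))
  vals <- vapply(starts, function(s) {
    mean((cs[s + window_len, ] - cs[s, ]) / window_len)
  }, numeric(1))
  structure(list(values = vals, window_len = as.integer(window_len),
                 step = as.integer(step), t0 = 0L),
            class = "energy_series")
}

#' Calibrate the segmentation threshold from an MVC energy series
#'
#' The detection threshold is set to twenty percent of the mean windowed
#' energy of the signer's maximal voluntary contraction.
#'
#' @param mvc_energy an `energy_series` computed on an MVC recording.
#' @return the threshold `T_R`.
#' @export
calibrate_threshold <- function(mvc_energy) {
  if (length(mvc_energy$values) == 0) stop("empty MVC energy series")
  0.20 * mean(mvc_energy$values)
}

#' Detect subword boundaries in an energy series
#'
#' Scans the series left to right for the five-window onset pattern
#' (`E(t), E(t+1), E(t+2) > T_R` with `E(t-1), E(t-2)` not above) and the
#' matching offset pattern (`E(t), E(t-1), E(t-2) > T_R` with
#' `E(t+1), E(t+2)` not above).  Each onset is matched to the next offset;
#' a segment still active at the end of the series is closed at the last
#' window.  Detections spanning 8 windows or fewer are discarded as
#' instant noise.  Patterns are evaluated only where all five windows
#' exist, and exact equality with the threshold counts as below.
#'
#' @param energy an `energy_series`.
#' @param T_R positive detection threshold.
#' @return a data frame with window indices `t_s`, `t_e` (0-based) and the
#'   derived 0-based inclusive sample indices `sample_start`,
#'   `sample_end`.
#' @export
detect_segments <- function(energy, T_R) {
  if (T_R <= 0) stop("T_R must be positive")
  e <- energy$values
  n <- length(e)
  out <- data.frame(t_s = integer(0), t_e = integer(0),
                    sample_start = integer(0), sample_end = integer(0))
  if (n < 5) return(out)
  above <- e > T_R
  # 0-based window indices where the full five-window context exists
  is_start <- function(t) {
    above[t + 1] && above[t + 2] && above[t + 3] &&
      !above[t] && !above[t - 1]
  }
  is_end <- function(t) {
    above[t + 1] && above[t] && above[t - 1] &&
      !above[t + 2] && !above[t + 3]
  }
  t <- 2L
  open_start <- NA_integer_
  while (t <= n - 3L) {
    if (is.na(open_start)) {
      if (is_start(t)) open_start <- t
    } else if (is_end(t)) {
      out <- rbind(out, data.frame(t_s = open_start, t_e = t,
                                   sample_start = NA, sample_end = NA))
      open_start <- NA_integer_
    }
    t <- t + 1L
  }
  if (!is.na(open_start)) {
    # recording ended while active: close at the last window
    out <- rbind(out, data.frame(t_s = open_start, t_e = n - 1L,
                                 sample_start = NA, sample_end = NA))
  }
  out <- out[out$t_e - out$t_s + 1L > 8L, , drop = FALSE]
  # window index t covers samples [t0 + t*step, t0 + t*step + window_len)
  out$sample_start <- energy$t0 + out$t_s * energy$step
  out$sample_end <- energy$t0 + out$t_e * energy$step +
    energy$window_len - 1L
  rownames(out) <- NULL
  out
}

#' Excise multi-channel segments at detected boundaries
#'
#' Applies boundaries detected on the dominant-hand sEMG energy verbatim to
#' all 8 sEMG and 6 ACC channels.
#'
#' @param recording an `slr_recording`.
#' @param boundaries data frame from [detect_segments()].
#' @return list of `subword_segment` objects in boundary order.
#' @export
extract_segments <- function(recording, boundaries) {
  n <- nrow(recording$emg)
  lapply(seq_len(nrow(boundaries)), function(i) {
    s0 <- boundaries$sample_start[i]; s1 <- boundaries$sample_end[i]
    if (s0 < 0 || s1 >= n) stop("boundary outside the recording")
    idx <- (s0 + 1L):(s1 + 1L)
    new_segment(recording$emg[idx, , drop = FALSE],
                recording$acc[idx, , drop = FALSE],
                sample_start = s0, sample_end = s1,
                fs_hz = recording$fs_hz)
  })
}

#' Segment a continuous recording end to end
#'
#' Convenience wrapper: windowed energy of the dominant-hand sEMG,
#' MVC-calibrated threshold, boundary detection and multi-channel
#' excision.
#'
#' @param recording recording to segment.
#' @param mvc MVC recording used for threshold calibration (or a
#'   precomputed numeric threshold).
#' @param window_len,step energy window parameters in samples.
#' @return list with `segments`, `boundaries` and the threshold `T_R`.
#' @export
segment_recording <- function(recording, mvc, window_len = 128L,
                              step = 64L) {
  T_R <- if (is.numeric(mvc)) mvc else
    calibrate_threshold(average_energy(mvc$emg[, 1:4], window_len, step))
  en <- average_energy(recording$emg[, 1:4], window_len, step)
  b <- detect_segments(en, T_R)
  list(segments = extract_segments(recording, b), boundaries = b,
       T_R = T_R)
}
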