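energy_series <- function(values, window_len = 128L, step = 64L) {
  structure(list(values = values, window_len = as.integer(window_len),
                 step = as.integer(step), t0 = 0L),
            class = "energy_series")
}

test_that("windowed average energy matches the channel-mean-square formula
           and a naive double loop", {
  const <- matrix(2, 256, 4)
  e <- average_energy(const)
  expect_true(all(e$values == 4))

  ramp <- matrix(rep(1:4, each = 256), 256, 4)
  expect_true(all(average_energy(ramp)$values == 7.5))

  set.seed(1)
  for (k in 1:100) {
    n <- sample(128:600, 1)
    x <- matrix(rnorm(n * 4, sd = runif(1, 0.1, 5)), n, 4)
    fast <- average_energy(x)$values
    expect_equal(fast, naive_energy(x), tolerance = 1e-12)
  }

  expect_error(average_energy(matrix(0, 256, 3)), "4")
  expect_error(average_energy(matrix(0, 64, 4)), "window_len")
})

test_that("the threshold is twenty percent of the mean MVC energy", {
  expect_equal(calibrate_threshold(energy_series(rep(10, 7))), 2)
  expect_equal(calibrate_threshold(energy_series(c(0, 20))), 2)
  expect_error(calibrate_threshold(energy_series(numeric(0))), "empty")

  mvc <- synthesize_mvc(seed = 3)
  en <- average_energy(mvc$emg[, 1:4])
  expect_equal(calibrate_threshold(en), 0.2 * mean(en$values))
})

test_that("boundary detection follows the five-window onset/offset rules,
           including the duration-8 rejection", {
  # hand-traced: onset at window 2, offset at window 10, duration 9 -> kept
  b <- detect_segments(energy_series(c(0,0,1,1,1,1,1,1,1,1,1,0,0)), 0.5)
  expect_equal(nrow(b), 1)
  expect_equal(b$t_s, 2L)
  expect_equal(b$t_e, 10L)
  # duration exactly 8 -> discarded
  b8 <- detect_segments(energy_series(c(0,0,1,1,1,1,1,1,1,1,0,0)), 0.5)
  expect_equal(nrow(b8), 0)
  # nothing above threshold
  expect_equal(nrow(detect_segments(energy_series(rep(0.1, 20)), 0.5)), 0)
  # equality counts as below: a run at exactly T_R never starts a segment
  expect_equal(nrow(detect_segments(energy_series(rep(0.5, 20)), 0.5)), 0)
  # active at the end of the series: closed at the last window
  bo <- detect_segments(energy_series(c(0, 0, rep(1, 12))), 0.5)
  expect_equal(nrow(bo), 1)
  expect_equal(bo$t_e, 13L)
  expect_error(detect_segments(energy_series(rep(1, 10)), 0), "positive")
})

test_that("window indices map to contiguous inclusive sample spans", {
  b <- detect_segments(energy_series(c(0,0,1,1,1,1,1,1,1,1,1,0,0),
                                     window_len = 128, step = 64), 0.5)
  expect_equal(b$sample_start, 2L * 64L)
  expect_equal(b$sample_end, 10L * 64L + 127L)
})

test_that("scaling the signal by c scales energy by c^2 and leaves
           boundaries unchanged under a c^2-scaled threshold", {
  set.seed(2)
  v <- make_vocabulary(3, seed = 2)
  rec <- synthesize_sentence(v, seed = 4)
  en1 <- average_energy(rec$emg[, 1:4])
  en2 <- average_energy(3 * rec$emg[, 1:4])
  expect_equal(en2$values, 9 * en1$values, tolerance = 1e-12)
  T_R <- calibrate_threshold(average_energy(synthesize_mvc(2)$emg[, 1:4]))
  expect_equal(detect_segments(en2, 9 * T_R), detect_segments(en1, T_R))
})

test_that("segments carry all 14 channels at the dominant-hand boundaries", {
  v <- make_vocabulary(2, seed = 3)
  rec <- synthesize_subword(v[[1]], seed = 1)
  n <- nrow(rec$emg)
  whole <- data.frame(t_s = 0L, t_e = 0L, sample_start = 0L,
                      sample_end = n - 1L)
  seg <- extract_segments(rec, whole)[[1]]
  expect_equal(seg$emg, rec$emg)
  expect_equal(seg$acc, rec$acc)
  bad <- whole; bad$sample_end <- n
  expect_error(extract_segments(rec, bad), "outside")

  two <- data.frame(t_s = c(0L, 0L), t_e = c(0L, 0L),
                    sample_start = c(0L, 500L), sample_end = c(399L, 899L))
  segs <- extract_segments(rec, two)
  expect_equal(nrow(segs[[1]]$emg), 400)
  expect_equal(segs[[2]]$sample_start, 500L)
})

test_that("segmentation recovers the subwords of synthetic sentences to
           within one window step", {
  T_R <- calibrate_threshold(
    average_energy(synthesize_mvc(seed = 1)$emg[, 1:4]))
  v <- make_vocabulary(4, seed = 10)
  hits <- 0; total <- 0
  for (s in 1:5) {
    rec <- synthesize_sentence(v[((s + 0:3) %% 4) + 1], seed = s)
    res <- segment_recording(rec, T_R)
    ann <- rec$annotations
    total <- total + nrow(ann)
    for (i in seq_len(nrow(ann))) {
      de <- abs(res$boundaries$sample_start - ann$t_start[i]) <= 64 &
        abs(res$boundaries$sample_end - ann$t_end[i]) <= 64
      hits <- hits + any(de)
    }
  }
  expect_gte(hits / total, 0.95)
})
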