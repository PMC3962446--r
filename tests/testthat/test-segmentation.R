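test_that("envelope of a pure in-band tone sits at the rectified-sine level", {
  fs <- 32000; a <- 0.1
  rec <- recording(a * sin(2 * pi * 3000 * (0:(fs - 1)) / fs), fs)
  env <- compute_envelope(rec)
  expect_length(env$level_db, fs)
  mid <- env$level_db[(fs / 4):(3 * fs / 4)]
  expect_lt(abs(mean(mid) - 20 * log10(2 * a / pi)), 1)
})

test_that("silence and out-of-band tones stay at the envelope floor", {
  fs <- 32000
  zero_env <- compute_envelope(recording(rep(0, fs), fs))
  expect_true(all(zero_env$level_db == -120))
  oob <- compute_envelope(recording(0.5 * sin(2 * pi * 100 * (0:(fs - 1)) / fs), fs))
  expect_lt(stats::median(oob$level_db), -60)
})

test_that("noise-floor estimator recovers a Gaussian level distribution", {
  set.seed(42)
  env <- structure(list(level_db = rnorm(1e6, -70, 2), fs_hz = 32000),
                   class = "log_envelope")
  nf <- estimate_noise_floor(env)
  expect_lt(abs(nf$mean_db - (-70)), 0.5)
  expect_lt(abs(nf$sd_db - 2), 0.3)
  expect_equal(nf$threshold_db, nf$mean_db + 4 * nf$sd_db)
})

test_that("noise-floor mode picks the majority component of a bimodal mix", {
  set.seed(7)
  lv <- c(rnorm(9e4, -70, 1.5), rnorm(1e4, -30, 1.5))
  nf <- estimate_noise_floor(lv)
  expect_lt(abs(nf$mean_db - (-70)), 1)
})

test_that("degenerate level histograms are rejected with advice", {
  expect_error(estimate_noise_floor(rep(-70, 1000)), "longer recording")
})

test_that("threshold detection returns maximal supra-threshold runs", {
  fs <- 1000
  lv <- rep(-70, fs)
  lv[101:180] <- -30   # one 80 ms run
  env <- structure(list(level_db = lv, fs_hz = fs), class = "log_envelope")
  segs <- detect_segments(env, -50)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$offset_s - segs$onset_s, 0.080, tolerance = 1e-9)
  expect_equal(segs$onset_s, 0.100, tolerance = 1e-9)
  empty <- detect_segments(env, 0)
  expect_equal(nrow(empty), 0)
})

test_that("refinement merges sub-threshold gaps before duration filtering", {
  tab <- function(on, off) {
    s <- songsvm:::.segment_table(on, off, fs_hz = 1000)
    s
  }
  # two 50 ms segments, 5 ms gap, threshold 10 -> one 105 ms segment
  r <- refine_segments(tab(c(0, 0.055), c(0.05, 0.105)), gap_threshold_ms = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$offset_s - r$onset_s, 0.105, tolerance = 1e-9)
  # isolated 15 ms segment removed
  r2 <- refine_segments(tab(0.1, 0.115), gap_threshold_ms = 10)
  expect_equal(nrow(r2), 0)
  # 12 ms gaps at threshold 10 remain split
  r3 <- refine_segments(tab(c(0, 0.062), c(0.05, 0.112)), gap_threshold_ms = 10)
  expect_equal(nrow(r3), 2)
  # fragments below 20 ms merged across small gaps survive (merge-then-delete)
  r4 <- refine_segments(tab(c(0, 0.015, 0.030), c(0.010, 0.025, 0.060)),
                        gap_threshold_ms = 10)
  expect_equal(nrow(r4), 1)
})

test_that("refinement is idempotent on random tables", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    on <- sort(runif(n, 0, 2))
    off <- on + runif(n, 0.005, 0.1)
    off <- pmin(off, c(on[-1] - 1e-4, Inf))
    raw <- songsvm:::.segment_table(on, off, fs_hz = 32000)
    once <- refine_segments(raw)
    twice <- refine_segments(once)
    expect_equal(unclass(twice), unclass(once))
  }
})

test_that("raising the threshold never increases total detected duration", {
  set.seed(6)
  lv <- -70 + 25 * abs(sin(seq(0, 40, length.out = 5000))) + rnorm(5000, 0, 2)
  env <- structure(list(level_db = lv, fs_hz = 1000), class = "log_envelope")
  total <- function(th) {
    s <- detect_segments(env, th)
    sum(s$offset_s - s$onset_s)
  }
  durs <- vapply(seq(-65, -45, by = 2), total, numeric(1))
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("bout grouping needs eight elements with sub-300 ms gaps", {
  mk <- function(n, gaps) {
    on <- cumsum(c(0, 0.05 + gaps))
    songsvm:::.segment_table(on, on + 0.05, fs_hz = 32000)
  }
  b8 <- detect_bouts(mk(8, rep(0.1, 7)))
  expect_equal(unique(b8$bout_id), 1L)
  b7 <- detect_bouts(mk(7, rep(0.1, 6)))
  expect_true(all(is.na(b7$bout_id)))
  split44 <- detect_bouts(mk(8, c(rep(0.1, 3), 0.4, rep(0.1, 3))))
  expect_true(all(is.na(split44$bout_id)))
})

test_that("segmentation recovers synthetic ground truth to the millisecond", {
  song <- clean_song()
  segs <- segment_recording(song$recording)
  truth <- song$truth
  expect_equal(nrow(segs), nrow(truth))
  expect_lt(max(abs(segs$onset_s - truth$onset_s)), 0.005)
  expect_lt(max(abs(segs$offset_s - truth$offset_s)), 0.005)
  # bout structure agrees with the generator's
  expect_equal(is.na(segs$bout_id), is.na(truth$bout_id))
})

test_that("estimated noise floor tracks the requested SNR within 2 dB", {
  song <- clean_song()
  env <- compute_envelope(song$recording)
  nf <- estimate_noise_floor(env)
  truth <- song$truth
  # median per-syllable peak envelope level above the floor
  peaks <- vapply(seq_len(nrow(truth)), function(k) {
    i <- (floor(truth$onset_s[k] * env$fs_hz) + 1):floor(truth$offset_s[k] * env$fs_hz)
    max(env$level_db[i])
  }, numeric(1))
  snr_est <- stats::median(peaks) - nf$mean_db
  expect_lt(abs(snr_est - attr(truth, "snr_db")), 2)
})
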