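fs <- 32000
tone <- function(f0, dur = 0.1, a = 1) a * sin(2 * pi * f0 * (0:(dur * fs - 1)) / fs)

test_that("differencing pre-filter removes DC and preserves length", {
  expect_equal(preprocess_segment(rep(3, 100)), c(0, rep(0, 99)))
  ramp <- preprocess_segment(0.5 * (1:100))
  expect_equal(ramp[-1], rep(0.5, 99))
  alt <- preprocess_segment(rep(c(1, -1), 50))
  expect_equal(abs(alt[-1]), rep(2, 99))
  expect_error(preprocess_segment(1), "too short")
})

test_that("spectrogram geometry follows the 256/64 frame convention", {
  sg <- syllable_spectrogram(numeric(640), fs)
  expect_equal(ncol(sg$mag), 7)          # (640 - 256) / 64 + 1
  expect_equal(nrow(sg$mag), 129)
  sg2 <- syllable_spectrogram(tone(4000), fs)
  peak_bin <- which.max(rowMeans(sg2$mag[-1, ]))
  expect_equal(peak_bin, 32)             # 4000 / 125 Hz per bin
  short <- syllable_spectrogram(numeric(100), fs)  # padded to one window
  expect_equal(ncol(short$mag), 1)
})

test_that("white-noise mean spectrum is approximately flat", {
  set.seed(8)
  sg <- syllable_spectrogram(rnorm(fs / 2), fs)
  m <- rowMeans(sg$mag[-1, ])
  mid <- m[5:124]
  expect_lt(stats::sd(mid) / mean(mid), 0.2)
})

test_that("five-point regression slope matches a least-squares oracle", {
  expect_equal(delta_series(rep(2, 10)), rep(0, 10))
  m <- 0.7
  d <- delta_series(m * (1:20))
  expect_equal(d[3:18], rep(m, 16))
  # short series against an explicit lm() on the replicated-edge window
  x <- c(1.3, -0.2, 2.5)
  d3 <- delta_series(x)
  oracle <- vapply(1:3, function(t) {
    idx <- pmin(pmax(t + (-2:2), 1), 3)
    unname(coef(lm(x[idx] ~ I(-2:2)))[2])
  }, numeric(1))
  expect_equal(d3, oracle, tolerance = 1e-12)
  expect_true(all(is.finite(d3)))
})

test_that("stationary tones have near-zero delta spectra; chirps do not", {
  sgt <- syllable_spectrogram(preprocess_segment(tone(3000)), fs)
  st <- mean_and_meanabs_delta(sgt)
  expect_lt(max(st$dspec) / max(st$spec), 0.05)
  chirp_f <- seq(2000, 6000, length.out = 0.1 * fs)
  chirp <- sin(2 * pi * cumsum(chirp_f) / fs)
  sgc <- syllable_spectrogram(preprocess_segment(chirp), fs)
  sc <- mean_and_meanabs_delta(sgc)
  expect_gt(max(sc$dspec) / max(sc$spec), 0.1)
})

test_that("cepstrum peaks at the fundamental's quefrency", {
  t <- (0:(0.1 * fs - 1)) / fs
  stack <- rowSums(sapply(1:6, function(h) sin(2 * pi * 1000 * h * t) / h))
  cp <- cepstra(syllable_spectrogram(preprocess_segment(stack), fs))
  expect_equal(which.max(cp$ceps[5:128]) + 4, 32)  # 1 ms at 32 kHz
  # white noise: cepstral energy confined near quefrency zero
  set.seed(9)
  cpn <- cepstra(syllable_spectrogram(rnorm(0.1 * fs), fs))
  expect_lt(max(abs(cpn$ceps[10:128])), 0.1)
  expect_true(all(is.finite(unlist(cp))) && all(is.finite(unlist(cpn))))
})

test_that("silent frames stay finite through the log floor", {
  cp <- cepstra(syllable_spectrogram(numeric(512), fs))
  expect_true(all(is.finite(cp$ceps)) && all(is.finite(cp$dceps)))
})

test_that("summary features behave like their acoustic definitions", {
  x <- preprocess_segment(tone(4000, dur = 0.08))
  sg <- syllable_spectrogram(x, fs)
  af <- acoustic_features(x, sg, fs)
  expect_equal(unname(af["duration_s"]), 0.08, tolerance = 1e-6)
  expect_equal(unname(af["zerocross_per_s"]), 4000, tolerance = 0.01)
  expect_equal(unname(af["centroid_hz"]), 4000, tolerance = 0.01)
  set.seed(10)
  xn <- preprocess_segment(rnorm(0.08 * fs))
  afn <- acoustic_features(xn, syllable_spectrogram(xn, fs), fs)
  expect_gt(unname(afn["entropy"]), unname(af["entropy"]))
})

test_that("every syllable yields 532 finite features in five blocks", {
  song <- clean_song()
  segs <- song$truth[1:3, ]
  m <- extract_features(song$recording, segs)
  expect_equal(dim(m), c(3, 532))
  expect_true(all(is.finite(unclass(m))))
  b <- attr(m, "blocks")
  expect_equal(vapply(b, length, integer(1)),
               c(spec = 128L, dspec = 128L, ceps = 128L, dceps = 128L, af = 20L))
  expect_equal(unname(unlist(b)), 1:532)
  empty <- extract_features(song$recording,
                            songsvm:::.segment_table(numeric(0), numeric(0)))
  expect_equal(dim(empty), c(0, 532))
})

test_that("features are deterministic and shift-invariant within a recording", {
  song <- clean_song()
  seg1 <- song$truth[5, ]
  twice <- extract_features(song$recording, song$truth[c(5, 5), ])
  expect_equal(twice[1, ], twice[2, ])
  # embed the same samples at a different offset in a fresh noiseless recording
  fs <- song$recording$fs_hz
  i <- (floor(seg1$onset_s * fs) + 1):floor(seg1$offset_s * fs)
  syl <- song$recording$samples[i]
  hop <- 64
  for (shift_frames in c(0, 3)) {
    pad <- 1000 + shift_frames * hop
    wave <- c(numeric(pad), syl, numeric(1000))
    rec <- recording(wave, fs)
    seg <- songsvm:::.segment_table(pad / fs, (pad + length(syl)) / fs, fs_hz = fs)
    f <- extract_features(rec, seg)
    if (shift_frames == 0) f0 <- f else
      expect_equal(unclass(f), unclass(f0), tolerance = 1e-6)
  }
})

test_that("gain scaling moves amplitude by 20 log10(g) and nothing else", {
  song <- clean_song()
  fs <- song$recording$fs_hz
  seg <- song$truth[7, ]
  g <- 3.5
  rec2 <- recording(song$recording$samples * g, fs)
  f1 <- extract_features(song$recording, song$truth[7, , drop = FALSE])
  f2 <- extract_features(rec2, song$truth[7, , drop = FALSE])
  a1 <- f1[1, "af.amplitude_db"]; a2 <- f2[1, "af.amplitude_db"]
  expect_equal(unname(a2 - a1), 20 * log10(g), tolerance = 1e-6)
  keep <- paste0("af.", c("centroid_hz", "skewness", "kurtosis", "entropy",
                          "peak_quefrency_s"))
  expect_equal(f1[1, keep], f2[1, keep], tolerance = 1e-6)
})

test_that("feature matrices round-trip through TSV losslessly", {
  song <- clean_song()
  m <- extract_features(song$recording, song$truth[1:4, ])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(m, path)
  m2 <- read_features(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-9)
  expect_equal(attr(m2, "labels"), attr(m, "labels"))
})
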