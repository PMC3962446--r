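# 532-dimensional acoustic feature vector per syllable:
#   spec 1:128 | dspec 129:256 | ceps 257:384 | dceps 385:512 | af 513:532

.AF_NAMES <- c("duration_s", "zerocross_per_s",
               "centroid_hz", "spread_hz", "skewness", "kurtosis",
               "entropy", "slope", "peak_quefrency_s", "pitch_goodness",
               "amplitude_db",
               paste0("d_", c("centroid_hz", "spread_hz", "skewness",
                              "kurtosis", "entropy", "slope",
                              "peak_quefrency_s", "pitch_goodness",
                              "amplitude_db")))

#' Column names of the 532-dimensional feature vector
#' @return Character vector of length 532 (`spec.001` ... `af.d_amplitude_db`).
#' @export
feature_names <- function() {
  c(sprintf("spec.%03d", 1:128), sprintf("dspec.%03d", 1:128),
    sprintf("ceps.%03d", 1:128), sprintf("dceps.%03d", 1:128),
    paste0("af.", .AF_NAMES))
}

#' Column blocks of the feature vector
#' @return Named list of integer column ranges for blocks `spec`, `dspec`,
#'   `ceps`, `dceps`, `af`.
#' @export
feature_blocks <- function() {
  list(spec = 1:128, dspec = 129:256, ceps = 257:384, dceps = 385:512,
       af = 513:532)
}

#' Differencing pre-filter
#'
#' First-difference high-pass filter removing baseline bias and slightly
#' emphasising high frequencies: `y[t] = x[t] - x[t-1]`, with `y[1] = 0` so
#' the length is preserved.
#'
#' @param x numeric waveform segment, length >= 2.
#' @return Filtered segment of the same length.
#' @export
preprocess_segment <- function(x) {
  if (length(x) < 2) stop("segment too short to preprocess")
  c(0, diff(x))
}

#' Magnitude spectrogram of a syllable
#'
#' Short-term Fourier transform with a hanning window, FFT size 256,
#' step 64. Segments shorter than one window are zero-padded to 256
#' samples (cannot occur after the 20 ms duration filter at fs >= 16 kHz,
#' but guarded).
#'
#' @param x waveform segment (typically already through
#'   [preprocess_segment()]).
#' @param fs_hz sampling rate.
#' @param n_fft FFT size (default 256).
#' @param step hop size in samples (default 64).
#' @return Object of class `spectrogram`: list with `mag` (129 x n_frames
#'   magnitudes, rows = bins 0..128 where row 1 is the DC bin),
#'   `freq_hz` (length 129), `frame_times_s`, `fs_hz`.
#' @export
syllable_spectrogram <- function(x, fs_hz, n_fft = 256, step = 64) {
  if (length(x) < n_fft) x <- c(x, numeric(n_fft - length(x)))
  n_frames <- (length(x) - n_fft) %/% step + 1
  starts <- (seq_len(n_frames) - 1) * step
  idx <- outer(seq_len(n_fft), starts, "+")
  frames <- matrix(x[idx], nrow = n_fft)
  w <- signal::hanning(n_fft)
  spec <- stats::mvfft(frames * w)
  mag <- Mod(spec[1:(n_fft / 2 + 1), , drop = FALSE])
  structure(list(mag = mag,
                 freq_hz = (0:(n_fft / 2)) * fs_hz / n_fft,
                 frame_times_s = (starts + n_fft / 2) / fs_hz,
                 fs_hz = fs_hz),
            class = "spectrogram")
}

#' Five-point regression slope along time
#'
#' Local least-squares slope over the window `t-2 .. t+2` for each row of a
#' (d x T) series: `delta[t] = sum_k k (x[t+k] - x[t-k]) / 10`, `k = 1, 2`.
#' Edges are handled by frame replication.
#'
#' @param m numeric matrix, variables in rows, time in columns (a plain
#'   vector is treated as one variable).
#' @return Matrix of the same shape with the per-frame slopes.
#' @export
delta_series <- function(m) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, nrow = 1)
  T <- ncol(m)
  pad <- function(k) pmin(pmax(seq_len(T) + k, 1), T)  # replicate edges
  d <- (1 * (m[, pad(1), drop = FALSE] - m[, pad(-1), drop = FALSE]) +
        2 * (m[, pad(2), drop = FALSE] - m[, pad(-2), drop = FALSE])) / 10
  if (vec) drop(d) else d
}

#' Mean spectrum and mean absolute delta-spectrum
#'
#' @param sg a `spectrogram`.
#' @return List with `spec` and `dspec`, each length 128 (DC excluded).
#' @export
mean_and_meanabs_delta <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  m <- sg$mag[-1, , drop = FALSE]  # drop DC bin
  list(spec = rowMeans(m), dspec = rowMeans(abs(delta_series(m))))
}

# per-frame real cepstra from a spectrogram: 128 x T (quefrency 1..128)
.frame_cepstra <- function(sg, n_fft = 256) {
  lm <- log(pmax(sg$mag, .LOG_FLOOR))            # 129 x T
  # symmetric extension of the log magnitude spectrum to the full FFT length
  ext <- rbind(lm, lm[(n_fft / 2):2, , drop = FALSE])  # 256 x T
  ceps <- Re(stats::mvfft(ext, inverse = TRUE)) / n_fft
  ceps[2:(n_fft / 2 + 1), , drop = FALSE]
}

#' Mean cepstrum and mean absolute delta-cepstrum
#'
#' The real cepstrum of each frame is the inverse Fourier transform of the
#' log magnitude spectrum (256-point, symmetric extension, magnitudes
#' floored before the log); quefrency coefficients 1..128 are kept (the 0th
#' is excluded) and averaged over frames. Deltas use the same five-point
#' regression as the spectrogram.
#'
#' @param sg a `spectrogram`.
#' @return List with `ceps` and `dceps`, each length 128.
#' @export
cepstra <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  cc <- .frame_cepstra(sg)
  list(ceps = rowMeans(cc), dceps = rowMeans(abs(delta_series(cc))))
}

# framewise 9-feature matrix (9 x T) from a spectrogram
.framewise_af <- function(sg) {
  mag <- sg$mag[-1, , drop = FALSE]              # bins 1..128
  f <- sg$freq_hz[-1]
  p <- mag^2
  T <- ncol(mag)

  colsum_mag <- colSums(mag)
  w <- sweep(mag, 2, pmax(colsum_mag, .LOG_FLOOR), "/")  # magnitude pmf
  centroid <- colSums(f * w)
  dev <- matrix(f, nrow = length(f), ncol = T) -
         matrix(centroid, nrow = length(f), ncol = T, byrow = TRUE)
  spread <- sqrt(colSums(dev^2 * w))
  safe_spread <- pmax(spread, 1e-9)
  skewness <- colSums(dev^3 * w) / safe_spread^3
  kurtosis <- colSums(dev^4 * w) / safe_spread^4

  # Wiener entropy (spectral flatness) of the power spectrum
  pf <- pmax(p, .LOG_FLOOR^2)
  entropy <- colMeans(log(pf)) - log(colMeans(pf))

  # spectral slope: least-squares slope of level (dB) vs frequency (Hz)
  ldb <- 20 * log10(pmax(mag, .LOG_FLOOR))
  fc <- f - mean(f)
  slope <- colSums(fc * ldb) / sum(fc^2)

  # peak quefrency searched over fundamentals 250 Hz - 4 kHz
  cc <- .frame_cepstra(sg)
  q_s <- seq_len(nrow(cc)) / sg$fs_hz
  q_keep <- which(q_s >= 1 / 4000 & q_s <= 1 / 250)
  cc_sub <- cc[q_keep, , drop = FALSE]
  peak_i <- max.col(t(cc_sub), ties.method = "first")
  peak_quefrency <- q_s[q_keep[peak_i]]
  pitch_goodness <- cc_sub[cbind(peak_i, seq_len(T))]

  rbind(centroid_hz = centroid, spread_hz = spread, skewness = skewness,
        kurtosis = kurtosis, entropy = entropy, slope = slope,
        peak_quefrency_s = peak_quefrency, pitch_goodness = pitch_goodness,
        amplitude_db = NA_real_)  # filled by acoustic_features (needs frames)
}

#' The twenty summary acoustic features of a syllable
#'
#' Duration; zero-cross rate (positive-to-negative crossings per second);
#' nine framewise features (spectral centroid, spread, skewness, kurtosis,
#' Wiener entropy, spectral slope, peak quefrency, pitch goodness,
#' amplitude) averaged over frames; and the nine matching delta features
#' (frame-averaged absolute five-point regression slopes).
#'
#' @param x waveform segment (after [preprocess_segment()]).
#' @param sg its `spectrogram`.
#' @param fs_hz sampling rate.
#' @return Named numeric vector of length 20.
#' @export
acoustic_features <- function(x, sg, fs_hz) {
  stopifnot(inherits(sg, "spectrogram"))
  duration_s <- length(x) / fs_hz
  zc <- sum(diff(x >= 0) == -1)  # positive-to-negative crossings
  zerocross_per_s <- zc / duration_s

  fw <- .framewise_af(sg)

  # frame amplitude: 10 log10 of mean squared sample within each frame
  n_fft <- 2 * (nrow(sg$mag) - 1)
  step <- if (ncol(sg$mag) > 1)
    round((sg$frame_times_s[2] - sg$frame_times_s[1]) * fs_hz) else 64
  xx <- if (length(x) < n_fft) c(x, numeric(n_fft - length(x))) else x
  starts <- (seq_len(ncol(sg$mag)) - 1) * step
  energy <- vapply(starts, function(s0)
    mean(xx[(s0 + 1):min(s0 + n_fft, length(xx))]^2), numeric(1))
  fw["amplitude_db", ] <- 10 * log10(pmax(energy, .LOG_FLOOR^2))

  d_fw <- abs(delta_series(fw))
  out <- c(duration_s, zerocross_per_s, rowMeans(fw), rowMeans(d_fw))
  names(out) <- .AF_NAMES
  out
}

#' Extract the 532-dimensional feature matrix for segmented syllables
#'
#' For each row of the segment table, the waveform inside the half-open
#' interval `[onset_s, offset_s)` is pre-filtered, transformed to a
#' spectrogram, and summarised as: 128 mean-spectrum values, 128 mean
#' absolute delta-spectrum values, 128 mean-cepstrum values, 128 mean
#' absolute delta-cepstrum values, and 20 summary acoustic features —
#' 532 features in total.
#'
#' @param rec a [recording].
#' @param segs a `segment_table` (labels, when present, are copied to the
#'   result's `"labels"` attribute).
#' @return `n x 532` numeric matrix of class `feature_matrix` with column
#'   names from [feature_names()] and attributes `labels` and `blocks`.
#' @export
extract_features <- function(rec, segs) {
  stopifnot(inherits(rec, "recording"), inherits(segs, "segment_table"))
  fs <- rec$fs_hz
  n <- nrow(segs)
  out <- matrix(NA_real_, nrow = n, ncol = 532,
                dimnames = list(NULL, feature_names()))
  for (k in seq_len(n)) {
    i1 <- floor(segs$onset_s[k] * fs) + 1
    i2 <- floor(segs$offset_s[k] * fs)
    if (i1 < 1 || i2 > length(rec$samples) || i2 <= i1)
      stop("segment ", k, " outside recording bounds")
    x <- preprocess_segment(rec$samples[i1:i2])
    sg <- syllable_spectrogram(x, fs)
    sp <- mean_and_meanabs_delta(sg)
    cp <- cepstra(sg)
    out[k, ] <- c(sp$spec, sp$dspec, cp$ceps, cp$dceps,
                  acoustic_features(x, sg, fs))
  }
  feature_matrix(out, labels = if (all(is.na(segs$label))) NULL else segs$label)
}

#' Construct a feature matrix object
#'
#' @param m numeric matrix with 532 columns (or a block subset produced by
#'   [select_feature_condition()]).
#' @param labels optional per-row label vector.
#' @param blocks named list of column ranges (defaults to the full
#'   532-column block structure when `m` has 532 columns).
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(m, labels = NULL, blocks = NULL) {
  m <- as.matrix(m)
  if (is.null(blocks)) {
    if (ncol(m) == 532) blocks <- feature_blocks()
    else stop("blocks must be given for non-532-column matrices")
  }
  if (!is.null(labels) && length(labels) != nrow(m))
    stop("labels length must match row count")
  structure(m, labels = if (is.null(labels)) NULL else as.character(labels),
            blocks = blocks, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d syllables x %d features (%s)%s\n",
              nrow(x), ncol(x),
              paste(names(attr(x, "blocks")), collapse = "+"),
              if (is.null(attr(x, "labels"))) "" else ", labeled"))
  invisible(x)
}

#' Subset a feature matrix to a named feature condition
#'
#' The seven conditions combine the blocks of the feature vector:
#' `Spec` = spectrum + delta spectrum (256 columns), `Ceps` = cepstrum +
#' delta cepstrum (256), `AF` = the 20 summary features, their pairwise
#' unions, and `ALL` (532).
#'
#' @param m a `feature_matrix` with the full 532 columns.
#' @param condition one of `"Spec"`, `"Ceps"`, `"AF"`, `"Spec+Ceps"`,
#'   `"Spec+AF"`, `"Ceps+AF"`, `"ALL"`.
#' @return A `feature_matrix` restricted to the condition's columns, with
#'   a matching `blocks` attribute.
#' @export
select_feature_condition <- function(m, condition = "ALL") {
  stopifnot(inherits(m, "feature_matrix"), ncol(m) == 532)
  condition <- match.arg(condition,
    c("ALL", "Spec", "Ceps", "AF", "Spec+Ceps", "Spec+AF", "Ceps+AF"))
  b <- feature_blocks()
  parts <- switch(condition,
    "ALL" = c("spec", "dspec", "ceps", "dceps", "af"),
    "Spec" = c("spec", "dspec"),
    "Ceps" = c("ceps", "dceps"),
    "AF" = "af",
    "Spec+Ceps" = c("spec", "dspec", "ceps", "dceps"),
    "Spec+AF" = c("spec", "dspec", "af"),
    "Ceps+AF" = c("ceps", "dceps", "af"))
  cols <- unlist(b[parts], use.names = FALSE)
  new_blocks <- list(); at <- 0
  for (p in parts) {
    new_blocks[[p]] <- at + seq_along(b[[p]])
    at <- at + length(b[[p]])
  }
  feature_matrix(unclass(m)[, cols, drop = FALSE],
                 labels = attr(m, "labels"), blocks = new_blocks)
}
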