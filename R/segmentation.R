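#' Construct a recording object
#'
#' @param samples numeric vector of audio samples, \eqn{\pm 1} full scale.
#' @param fs_hz sampling rate in Hz. Must exceed 16 kHz so that the 1--8 kHz
#'   analysis band lies below Nyquist.
#' @param source free-text provenance string.
#' @return An object of class `recording`: a list with elements `samples`,
#'   `fs_hz`, `source`.
#' @export
recording <- function(samples, fs_hz, source = "") {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (fs_hz <= 2 * 8000)
    stop("fs_hz must exceed 16 kHz (band-pass upper edge 8 kHz below Nyquist)")
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 source = as.character(source)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %.2f s at %d Hz (%s)\n",
              length(x$samples) / x$fs_hz, as.integer(x$fs_hz),
              if (nzchar(x$source)) x$source else "in memory"))
  invisible(x)
}

#' Log-amplitude envelope of a recording
#'
#' Band-pass filters the waveform to the 1--8 kHz song band, extracts the
#' amplitude envelope by full-wave rectification and 200 Hz low-pass
#' filtering, and converts to relative sound level in dB. Both filters are
#' 4th-order Butterworth applied forward-backward (zero phase) so syllable
#' boundaries are not lagged. The envelope is clipped at \eqn{-120} dB re
#' full scale before the log so digital silence stays finite.
#'
#' @param rec a [recording].
#' @param band_hz band-pass edges in Hz, default `c(1000, 8000)`.
#' @param lp_hz envelope low-pass cutoff in Hz, default 200.
#' @return An object of class `log_envelope`: list with `level_db` (same
#'   length as the input) and `fs_hz`.
#' @export
compute_envelope <- function(rec, band_hz = c(1000, 8000), lp_hz = 200) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs_hz
  if (band_hz[2] >= fs / 2) stop("band-pass upper edge must be below Nyquist")
  if (length(rec$samples) < 3 * fs %/% lp_hz)
    stop("recording too short for envelope filters")
  bp <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, rec$samples)
  lp <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  env <- signal::filtfilt(lp, abs(x))
  floor_lin <- 10^(.ENV_FLOOR_DB / 20)
  level <- 20 * log10(pmax(env, floor_lin))
  structure(list(level_db = level, fs_hz = fs), class = "log_envelope")
}

#' Estimate the background-noise floor from a level histogram
#'
#' In recordings of an isolated bird the background level is constant, and
#' silence dominates the recording, so the mode of the sound-level histogram
#' is the mean noise level. Spread is estimated from the full width at half
#' maximum of the histogram peak (FWHM = 2.3548 SD for a Gaussian), and the
#' detection threshold is set at the mean plus 4 standard deviations.
#'
#' @param env a `log_envelope` (or any numeric vector of dB levels).
#' @param bin_db histogram bin width in dB (default 0.5).
#' @param sd_multiplier threshold offset in noise SDs above the mean
#'   (default 4).
#' @return Object of class `noise_floor`: list with `mean_db`, `sd_db`,
#'   `threshold_db`.
#' @export
estimate_noise_floor <- function(env, bin_db = 0.5, sd_multiplier = 4) {
  level <- if (inherits(env, "log_envelope")) env$level_db else as.numeric(env)
  level <- level[is.finite(level)]
  if (!length(level)) stop("no finite levels to histogram")

  lo <- floor(min(level) / bin_db) * bin_db
  hi <- ceiling(max(level) / bin_db) * bin_db
  if (hi <= lo) hi <- lo + bin_db
  breaks <- seq(lo, hi + bin_db, by = bin_db)
  counts <- tabulate(findInterval(level, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  centers <- breaks[-length(breaks)] + bin_db / 2

  if (sum(counts > 0) < 2)
    stop("degenerate level histogram (all levels in one bin); ",
         "use a longer recording containing background noise")

  mode_i <- which.max(counts)
  mean_db <- centers[mode_i]
  half <- counts[mode_i] / 2

  # FWHM by linear interpolation at the half-maximum crossings around the mode
  cross_left <- NA_real_
  for (i in seq(mode_i, 2)) {
    if (counts[i - 1] < half && counts[i] >= half) {
      frac <- (half - counts[i - 1]) / (counts[i] - counts[i - 1])
      cross_left <- centers[i - 1] + frac * bin_db
      break
    }
  }
  cross_right <- NA_real_
  if (mode_i < length(counts)) {
    for (i in seq(mode_i, length(counts) - 1)) {
      if (counts[i] >= half && counts[i + 1] < half) {
        frac <- (counts[i] - half) / (counts[i] - counts[i + 1])
        cross_right <- centers[i] + frac * bin_db
        break
      }
    }
  }
  if (is.na(cross_left) || is.na(cross_right))
    stop("could not measure the FWHM of the noise peak; ",
         "use a longer recording containing background noise")

  sd_db <- (cross_right - cross_left) / (2 * sqrt(2 * log(2)))
  if (sd_db <= 0) stop("non-positive noise spread estimate")
  structure(list(mean_db = mean_db, sd_db = sd_db,
                 threshold_db = mean_db + sd_multiplier * sd_db),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("<noise_floor> mean %.2f dB, sd %.2f dB, threshold %.2f dB\n",
              x$mean_db, x$sd_db, x$threshold_db))
  invisible(x)
}

.segment_table <- function(onset_s, offset_s, label = NA_character_,
                           bout_id = NA_integer_, fs_hz = NA_real_) {
  n <- length(onset_s)
  if (length(label) != n) label <- rep(as.character(label), length.out = n)
  if (length(bout_id) != n) bout_id <- rep(as.integer(bout_id), length.out = n)
  df <- data.frame(onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   label = as.character(label),
                   bout_id = as.integer(bout_id),
                   stringsAsFactors = FALSE)
  attr(df, "fs_hz") <- fs_hz
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Detect supra-threshold sound segments
#'
#' Returns the maximal runs of envelope samples above the detection
#' threshold, in seconds, using half-open intervals `[onset, offset)`.
#'
#' @param env a `log_envelope`.
#' @param floor a `noise_floor` (or a single numeric threshold in dB).
#' @return A `segment_table` data frame with columns `onset_s`, `offset_s`,
#'   `label`, `bout_id`.
#' @export
detect_segments <- function(env, floor) {
  stopifnot(inherits(env, "log_envelope"))
  thr <- if (inherits(floor, "noise_floor")) floor$threshold_db else as.numeric(floor)
  above <- env$level_db > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(.segment_table(numeric(0), numeric(0), fs_hz = env$fs_hz))
  .segment_table((starts[keep] - 1) / env$fs_hz, ends[keep] / env$fs_hz,
                 fs_hz = env$fs_hz)
}

#' Refine raw segments into syllables
#'
#' Applies the two elimination rules in a fixed order: first every
#' inter-segment gap shorter than `gap_threshold_ms` is merged (fusing its
#' neighbours — merging first prevents deleting fragmented syllables), then
#' every segment shorter than `min_syllable_ms` is removed.
#'
#' @param raw a raw `segment_table` from [detect_segments()].
#' @param min_syllable_ms minimum syllable duration in ms (default 20).
#' @param gap_threshold_ms gap elimination threshold in ms; chosen per bird
#'   in the 3--10 ms range (default 5). Values outside `[3, 10]` are allowed
#'   but flagged with a message.
#' @return A refined `segment_table`.
#' @export
refine_segments <- function(raw, min_syllable_ms = 20, gap_threshold_ms = 5) {
  stopifnot(inherits(raw, "segment_table"))
  if (gap_threshold_ms < 3 || gap_threshold_ms > 10)
    message("gap_threshold_ms = ", gap_threshold_ms,
            " is outside the usual 3-10 ms range")
  fs <- attr(raw, "fs_hz")
  if (nrow(raw) == 0) return(raw)
  on <- raw$onset_s; off <- raw$offset_s

  if (nrow(raw) > 1) {
    gaps <- on[-1] - off[-nrow(raw)]
    # new group whenever the preceding gap is at least the threshold
    grp <- cumsum(c(1, gaps >= gap_threshold_ms / 1000))
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  dur_ok <- (off - on) >= min_syllable_ms / 1000 - 1e-12
  .segment_table(as.numeric(on[dur_ok]), as.numeric(off[dur_ok]), fs_hz = fs)
}

#' Group syllables into song bouts
#'
#' A bout is a succession of eight or more sound elements whose
#' inter-element gaps all last less than 300 ms. Qualifying runs receive
#' consecutive `bout_id`s; other segments keep `NA`.
#'
#' @param segs a refined `segment_table`.
#' @param max_gap_s maximum intra-bout gap in seconds (default 0.3).
#' @param min_elements minimum number of elements per bout (default 8).
#' @return The table with `bout_id` filled in.
#' @export
detect_bouts <- function(segs, max_gap_s = 0.3, min_elements = 8) {
  stopifnot(inherits(segs, "segment_table"))
  n <- nrow(segs)
  if (n == 0) return(segs)
  grp <- if (n == 1) 1L else
    cumsum(c(1, (segs$onset_s[-1] - segs$offset_s[-n]) >= max_gap_s))
  sizes <- table(grp)
  qualifying <- as.integer(names(sizes)[sizes >= min_elements])
  bout_id <- rep(NA_integer_, n)
  for (k in seq_along(qualifying))
    bout_id[grp == qualifying[k]] <- k
  segs$bout_id <- bout_id
  segs
}

#' Segment a recording end to end
#'
#' Convenience wrapper running envelope extraction, noise-floor estimation,
#' threshold detection, refinement, and bout grouping.
#'
#' @inheritParams compute_envelope
#' @inheritParams refine_segments
#' @inheritParams estimate_noise_floor
#' @return A `segment_table` with the `noise_floor` attached as attribute
#'   `"noise_floor"`.
#' @export
segment_recording <- function(rec, gap_threshold_ms = 5, min_syllable_ms = 20,
                              sd_multiplier = 4) {
  env <- compute_envelope(rec)
  nf <- estimate_noise_floor(env, sd_multiplier = sd_multiplier)
  segs <- detect_segments(env, nf)
  segs <- refine_segments(segs, min_syllable_ms = min_syllable_ms,
                          gap_threshold_ms = gap_threshold_ms)
  segs <- detect_bouts(segs)
  attr(segs, "noise_floor") <- nf
  segs
}
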