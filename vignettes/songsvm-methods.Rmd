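---
title: "Methods: segmentation, features, classification, and accuracy estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, features, classification, and accuracy estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songsvm)
```

# Overview

Birdsong research — in particular work on the Bengalese finch, whose songs
string brief vocal elements (syllables) into complex sequences — needs every
syllable in long recordings parsed and labeled before any sequence analysis
can start. A single bird produces tens of thousands of syllables per day, so
fully manual labeling does not scale. `songsvm` implements a semi-automatic
pipeline: syllables are segmented automatically, an expert labels a small
*instruction set* (on the order of one minute of song), a linear soft-margin
support vector machine (SVM) learns the labels in a high-dimensional acoustic
feature space, and the machine labels the rest. Finally, the classifier's own
margin scores are used to *estimate* the labeling accuracy of the whole
dataset from a small, score-stratified verified subset, so the user knows how
much to trust the output without checking it all.

This vignette documents the models and the numerical choices, what the
synthetic-song generator emulates, and what the package's validation does and
does not show about real recordings.

# Syllable segmentation

The segmenter assumes a single bird recorded in a sound-proof box, so the
background-noise level is constant over a recording. The waveform is
band-pass filtered to the 1–8 kHz song band, full-wave rectified, and
low-pass filtered at 200 Hz to give the amplitude envelope, expressed in dB.
Both filters are 4th-order Butterworth run forward–backward (`filtfilt`), so
the envelope has zero phase lag and detected boundaries are not biased late;
the design only fixes the band edges, and zero-phase application is our
choice to keep boundaries honest. The envelope is clipped at −120 dB re full
scale before the log so that digital silence stays finite.

Because silence dominates a typical recording (the stated assumption is at
least half non-song time), the mode of the envelope-level histogram is the
mean background level. The spread is read off the full width at half maximum
of that histogram peak; for a Gaussian peak FWHM = 2.3548 σ, which is the
conversion used. Numerical choices: 0.5 dB histogram bins, FWHM crossings
located by linear interpolation between adjacent bins. A histogram with only
one occupied bin, or no half-maximum crossing on either side, raises an
error asking for a longer recording rather than guessing. The detection
threshold is the mean noise level + 4 SD.

Supra-threshold runs become raw segments (seconds, half-open intervals
`[onset, offset)`). Two elimination rules then apply, deliberately in this
order: gaps shorter than the per-bird gap threshold (3–10 ms, default 5 ms)
are merged first, and only then are segments shorter than 20 ms deleted.
Merging first means a syllable fragmented by a brief envelope dip is fused
back together before the duration filter could throw its fragments away. We
read "eliminating" a short gap as fusing its two neighbours into one
syllable. Bouts are maximal runs of at least eight elements whose gaps are
all under 300 ms.

# The 532-dimensional feature vector

Each segmented syllable is summarised by 532 features in five blocks:

| block | content | dimensions |
|---|---|---|
| spec | mean magnitude spectrum | 128 |
| dspec | mean absolute delta spectrum | 128 |
| ceps | mean real cepstrum | 128 |
| dceps | mean absolute delta cepstrum | 128 |
| af | duration, zero-cross rate, 9 framewise summaries + their 9 deltas | 20 |

The waveform is first passed through a differencing filter (`y[t] = x[t] −
x[t−1]`) to remove baseline bias and slightly emphasise high frequencies,
then transformed with a short-term Fourier transform (Hann window, FFT 256,
hop 64; 125 Hz per bin at 32 kHz). The DC bin is excluded everywhere, for
the framewise summary features as well as the spectrum itself, so all blocks
see the same 128 bins. Temporal derivatives use the classic five-point
regression slope `Δ[t] = Σ_k k·(x[t+k] − x[t−k]) / 10`, k = 1..2, with
replicated edge frames; absolute slopes are averaged over frames.

The real cepstrum is computed per frame — inverse FFT of the log magnitude
spectrum, symmetric 256-point extension, magnitudes floored at 1e-10 before
the log — and then averaged over frames, keeping quefrency coefficients
1–128. Averaging the spectrogram first and taking one cepstrum of the mean
spectrum would be the other reading of "transform and average"; the
per-frame order was chosen because it also supplies the per-frame cepstra
that the delta-cepstrum and the framewise pitch features need.

The nine framewise summaries are computed per frame and averaged, rather
than computed once on the mean spectrum, because their temporal derivatives
must exist as framewise series. They are: spectral centroid, spread,
skewness, and kurtosis (moments of the normalised magnitude spectrum over
bin center frequencies); Wiener entropy (log ratio of geometric to
arithmetic mean of the power spectrum — high for noise, near −∞ for pure
tones); spectral slope (least-squares slope of level in dB against frequency
in Hz); peak quefrency and pitch goodness (location and height of the
cepstral peak, searched over quefrencies corresponding to 250 Hz–4 kHz
fundamentals — the plausible range for finch syllables; no search range is
inherent in the definition); and amplitude (frame mean of 10·log10 frame
energy). Zero-cross rate counts positive-to-negative crossings over the
whole syllable divided by its duration, so a pure tone at f0 scores ≈ f0.

# Classifier

Features are z-standardised before training. The four 128-wide blocks are
standardised with one pooled mean and SD per block — per-coefficient
standardisation would rescale each spectral bin separately and destroy the
covariance structure across bins — while the 20 summary features, which live
on unrelated scales (seconds, Hz, dB), are standardised per column. A
constant column (SD < 1e-12) maps to 0 and is flagged. Factors fitted on the
training fold are reused verbatim on test data.

The classifier is a set of one-vs-rest binary linear soft-margin SVMs, one
evaluation axis per class, with the soft-margin cost c fixed at 1:
performance is flat from about c = 10⁻² to 10⁴ on separable song data (the
test suite checks the plateau), so nothing is tuned. Three solver variants
are available — L2-regularised L2-loss (2R-2L, default), L2-regularised
L1-loss (2R-1L), and L1-regularised L2-loss (1R-2L) — implemented in
compiled code as dual coordinate descent (2R-x L) and primal coordinate
Newton descent with Armijo line search (1R-2L). The bias enters by unit
augmentation. Solver tolerance is 1e-4 with at most 10 000 sweeps, and the
internal coordinate ordering uses a fixed private PRNG, so training is
deterministic and never touches R's RNG stream. The test suite cross-checks
the learned hyperplane against an independent SVM implementation
(`e1071::svm`, linear kernel) on toy data.

A sample's decision value on axis k is `w_k·x + b_k`; in these units the
class boundary is 0 and the margins are ±1 by the soft-margin construction,
so the raw decision value is already on the normalised scale — no division
by the weight norm. The predicted label is the argmax axis and the
**evaluation score** is the maximum decision value: a confidence index that
is low when the sample resembles no trained class. Thresholding on it labels
unreliable syllables `"unknown"` instead of forcing a class.

PCA reduction (for the dimensionality experiments) fits loadings on the
standardised training fold only and projects test data with those loadings.

# Validation protocols

`run_eval1` implements the idealised protocol: equalised per-type pools,
L randomly drawn label classes × N training and 10 test samples per class,
re-drawn 30 × 20 = 600 times by default (test and benchmark runs use fewer
replicates; the replicate grid is a parameter). `run_eval2` implements the
realistic protocol: syllables at natural occurrence rates, training sets
sized by recording duration. Duration maps to a syllable count through the
corpus's mean syllable rate (count × duration / corpus duration), since
sampling is per syllable but the practical unit of manual effort is seconds
of recording; in the full-corpus condition 10 random samples (about one
second of song) are held out instead. Correct rate (CR) and Cohen's kappa
Κ = (CR − c)/(1 − c) are reported with the chance level c = 1/L — the
inverse number of types, not Cohen's empirical-marginal chance, which is the
right reference when label subsets are drawn uniformly.

# Accuracy estimation for large datasets

To estimate the correct rate of a classifier output too large to verify, up
to 50 samples are drawn at each of nine locations on the evaluation-score
axis (−0.8 to 0.8 in steps of 0.2, the region spanning the margins; window
±0.1, nearest-first, ties broken by index), giving at most 450 syllables to
verify regardless of corpus size. A logistic curve
`CR(s) = 1/(1 + exp(−(a + b·s)))` is fitted to the verified per-sample
outcomes pooled across locations — fitting raw binary outcomes rather than
the nine binned rates targets the same curve but behaves better when low
-score bins are sparse (both inputs are accepted; pooled-raw is the
default). Complete separation (e.g. every verified sample correct) is
caught and refitted with weakly weighted split pseudo-observations at the
score extremes; a negative fitted slope is reported with a warning, not
hidden.

The occurrence density of scores is built from proportional histograms (bin
0.1) per source (bird/recording), averaged across sources so unequal corpus
sizes do not bias the density, then smoothed with a Gaussian kernel
(bandwidth 0.15) and renormalised on a fixed grid (`[min − 1, max + 1]`,
step 0.01, trapezoidal integration). The product CR(s)·p(s) is the correct
-label density; its integral is the overall correct-rate estimate, and its
running integral from high to low score is the convergence curve. The same
two objects give the retention trade-off: mass above a rejection threshold
versus density-weighted CR among retained syllables.

# The synthetic-song generator

All validation runs on synthetic song with exact ground truth. Syllable
classes are harmonic stacks (amplitude 1/h per harmonic) on linearly
chirping fundamentals, mixed with band-limited noise in a per-class
proportion, under 5 ms raised-cosine ramps (sharp enough for unambiguous
boundaries, smooth enough to avoid spectral splatter). Sequences follow a
ring-biased first-order Markov chain; bouts of 8–14 syllables with 20–150 ms
gaps are separated by 1 s of silence. The background is white Gaussian noise
low-passed at 10 kHz at a constant level (−55 dB re full scale), matching
the constant-floor assumption of the segmenter. Since detection operates in
the 1–8 kHz band, syllable levels are set relative to the in-band noise
floor (7/10 of the broadband power), so the requested SNR is what the noise
-floor estimator actually sees. Renditions jitter in duration, level
(SD 1–2.5 dB), and fundamental (1–3%), emulating rendition variability.

Two presets: `"clean"` (carriers ≥ 500 Hz apart, low jitter) is the
idealised regime in which classification should be essentially perfect, and
is used for the segmentation and cross-validation benchmarks at 30 dB SNR
with 64 renditions per class. `"variable"` adds a weak (−12 dB), noisy
(noise fraction 0.5), strongly jittered introductory class concentrated at
bout onsets — emulating the unstable bout-initial syllables of real song —
plus a confusable class pair 250 Hz apart and stronger jitter; it exists
because margin-score spread and PCA information loss, the phenomena the
accuracy-estimation and dimensionality checks measure, do not occur when
classes are trivially separable. Benchmark problem sizes (e.g. 100-replicate
cross-validation sweeps, a 10 000-syllable corpus for the estimation
recovery check) are chosen as the smallest sizes at which the measured
quantities are stable.

What passing these tests does **not** show: real recordings have
reverberation, cage noise, overlapping calls, non-stationary floors
(excluded by assumption), and within-class acoustic drift far richer than
jittered harmonic stacks. The synthetic results validate the machinery —
boundary recovery, feature geometry, margin calibration, estimator
consistency — not field performance on any particular bird.

# Known limitations

* The noise-floor estimator requires majority-silence recordings and a
  constant floor; it has no tracking mode.
* Gap and duration thresholds are global per run; birds with bimodal gap
  statistics may need per-file configuration.
* The logistic correct-rate curve is monotone by construction; a classifier
  whose errors concentrate at *high* scores (e.g. systematic label swaps)
  would violate the model and the estimate would not flag it.
* Overlapping vocalisations (duetting) are out of scope.
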