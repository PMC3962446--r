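# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

clean_grammar <- function() fixture("clean_grammar", function()
  bf_grammar(7, "clean", seed = 1))

variable_grammar <- function() fixture("variable_grammar", function()
  bf_grammar(7, "variable", seed = 1))

# ~10 bouts, ~120 syllables, 30 dB SNR, with ground truth
clean_song <- function() fixture("clean_song", function()
  make_recording(clean_grammar(), n_bouts = 10, snr_db = 30, seed = 2))

# labeled pool, 24 renditions x 7 classes at 30 dB
clean_pool <- function() fixture("clean_pool", function()
  synth_feature_pool(clean_grammar(), n_per_class = 24, snr_db = 30, seed = 11))

# toy 2-d separated gaussian clouds as a labeled feature matrix
toy_clouds <- function(n = 50, sep = 2, sd = 0.1, seed = 3) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, sep, sd), rnorm(n, 0, sd)),
             cbind(rnorm(n, -sep, sd), rnorm(n, 0, sd)))
  feature_matrix(X, labels = rep(c("a", "b"), each = n),
                 blocks = list(x = 1:2))
}
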