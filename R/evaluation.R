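#' Correct classification rate
#'
#' @param predicted,truth equal-length label vectors.
#' @return Fraction of exact matches, in `[0, 1]`.
#' @export
correct_rate <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!length(predicted)) stop("empty label vectors")
  mean(as.character(predicted) == as.character(truth))
}

#' Cohen's kappa against the 1/L chance level
#'
#' Chance-corrected correct rate `K = (CR - c) / (1 - c)` where the chance
#' level `c` is the inverse of the number of label classes (not the
#' empirical label-frequency expectation of Cohen's original formulation —
#' appropriate when label subsets are drawn with equal rates).
#'
#' @param cr correct rate in `[0, 1]`.
#' @param n_labels number of label classes L (>= 2).
#' @return Kappa value.
#' @export
cohens_kappa <- function(cr, n_labels) {
  if (n_labels < 2) stop("n_labels must be at least 2")
  stopifnot(all(cr >= 0 & cr <= 1))
  c0 <- 1 / n_labels
  (cr - c0) / (1 - c0)
}

#' Cross-validation sweep over labels and training-set sizes
#'
#' The idealised protocol: from a pool with equalised per-type counts,
#' draw `L` label classes at random (`n_label_draws` times) and, for each,
#' draw `N` training and `n_test_per_label` test samples per class with no
#' overlap (`n_sample_draws` times). Each replicate standardises features
#' on its training fold, trains a linear SVM, and scores the test fold.
#' The default 30 x 20 grid yields 600 replicates per condition.
#'
#' @param pool labeled `feature_matrix` (every type needs at least
#'   `N + n_test_per_label` samples).
#' @param L number of label classes per replicate.
#' @param N training samples per label.
#' @param feature_condition see [select_feature_condition()].
#' @param solver see [svm_train()].
#' @param n_label_draws,n_sample_draws replicate grid (default 30 x 20).
#' @param n_test_per_label test samples per label (default 10).
#' @param pca_components optionally reduce each replicate's features to
#'   this many principal components (fitted on the training fold only).
#' @param cost_c soft-margin cost (default 1).
#' @param seed integer seed.
#' @return Object of class `cv_result`: list with the condition, the
#'   per-replicate `correct_rates` and `kappas`, and `summary`
#'   (mean/sd CR, mean kappa).
#' @export
run_eval1 <- function(pool, L, N, feature_condition = "ALL",
                      solver = "2R-2L", n_label_draws = 30,
                      n_sample_draws = 20, n_test_per_label = 10,
                      pca_components = NULL, cost_c = 1, seed = 1) {
  stopifnot(inherits(pool, "feature_matrix"))
  labels <- attr(pool, "labels")
  if (is.null(labels)) stop("pool must be labeled")
  types <- sort(unique(labels))
  counts <- table(labels)
  if (length(types) < L) stop("pool has fewer than L label types")
  need <- N + n_test_per_label
  if (any(counts < need))
    stop("every type needs at least N + ", n_test_per_label, " samples")

  cond <- if (ncol(pool) == 532) select_feature_condition(pool, feature_condition)
          else if (feature_condition == "ALL") pool
          else stop("named feature conditions need the full 532-column matrix")
  x <- unclass(as.matrix(cond))
  blocks <- attr(cond, "blocks")

  crs <- numeric(0)
  with_seed(seed, {
    for (ld in seq_len(n_label_draws)) {
      chosen <- sample(types, L)
      for (sd_ in seq_len(n_sample_draws)) {
        tr_idx <- integer(0); te_idx <- integer(0)
        for (cl in chosen) {
          idx <- sample(which(labels == cl), need)
          tr_idx <- c(tr_idx, idx[seq_len(N)])
          te_idx <- c(te_idx, idx[N + seq_len(n_test_per_label)])
        }
        tr <- feature_matrix(x[tr_idx, , drop = FALSE],
                             labels = labels[tr_idx], blocks = blocks)
        te <- feature_matrix(x[te_idx, , drop = FALSE],
                             labels = labels[te_idx], blocks = blocks)
        sc <- fit_scaling(tr)
        tr <- apply_scaling(tr, sc)
        te <- apply_scaling(te, sc)
        if (!is.null(pca_components)) {
          red <- pca_reduce(tr, te, pca_components)
          tr <- red$train; te <- red$test
        }
        model <- svm_train(tr, solver = solver, cost_c = cost_c,
                           feature_condition = feature_condition)
        pred <- svm_predict(model, te)
        crs <- c(crs, correct_rate(pred$predicted_label, labels[te_idx]))
      }
    }
  })
  structure(list(
    condition = list(L = L, N = N, feature_condition = feature_condition,
                     solver = solver, pca_components = pca_components,
                     cost_c = cost_c),
    correct_rates = crs,
    kappas = cohens_kappa(crs, L),
    summary = list(mean_cr = mean(crs), sd_cr = stats::sd(crs),
                   mean_kappa = mean(cohens_kappa(crs, L)))),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d replicates, mean CR %.2f%% (sd %.2f), mean kappa %.3f\n",
              length(x$correct_rates), 100 * x$summary$mean_cr,
              100 * (x$summary$sd_cr %||% 0), x$summary$mean_kappa))
  invisible(x)
}

#' Cross-validation under realistic occurrence rates
#'
#' The realistic protocol: syllables are drawn from a corpus at their
#' natural occurrence rates (including introductory and noisy types). Per
#' replicate, training syllables amounting to `duration_s` seconds of
#' recording — converted to a count through the corpus's mean syllable
#' rate — are selected at random; the remainder is the test fold. In the
#' full-corpus condition (`duration_s == corpus_duration_s`) the test fold
#' is instead a random 10 samples (about one second of song) and all other
#' samples train. Correct rate and Cohen's kappa (chance level 1/L with L
#' the corpus's number of types) are reported per replicate.
#'
#' @param corpus labeled `feature_matrix` for the whole corpus.
#' @param corpus_duration_s total recording duration the corpus came from.
#' @param duration_s training-duration condition in seconds (e.g. 15, 30,
#'   60, 90, 120 for a 120-s corpus).
#' @param n_reps replicates (default 600).
#' @param solver,feature_condition,cost_c classifier settings (defaults
#'   2R-2L, ALL, 1).
#' @param scaling optional precomputed corpus-level `scaling_factors`;
#'   when `NULL`, factors are refitted on each training fold.
#' @param n_test_full test-fold size in the full-corpus condition
#'   (default 10).
#' @param seed integer seed.
#' @return A `cv_result`.
#' @export
run_eval2 <- function(corpus, corpus_duration_s, duration_s, n_reps = 600,
                      solver = "2R-2L", feature_condition = "ALL",
                      cost_c = 1, scaling = NULL, n_test_full = 10,
                      seed = 1) {
  stopifnot(inherits(corpus, "feature_matrix"))
  labels <- attr(corpus, "labels")
  if (is.null(labels)) stop("corpus must be labeled")
  if (duration_s > corpus_duration_s)
    stop("duration condition exceeds the corpus duration")
  n <- nrow(corpus)
  L <- length(unique(labels))
  full <- abs(duration_s - corpus_duration_s) < 1e-9
  n_train <- if (full) n - n_test_full
             else round(n * duration_s / corpus_duration_s)
  if (n_train < 2 || n_train >= n)
    stop("training size ", n_train, " out of range for corpus of ", n)

  cond <- if (ncol(corpus) == 532) select_feature_condition(corpus, feature_condition)
          else if (feature_condition == "ALL") corpus
          else stop("named feature conditions need the full 532-column matrix")
  x <- unclass(as.matrix(cond))
  blocks <- attr(cond, "blocks")

  crs <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      repeat {
        tr_idx <- sample.int(n, n_train)
        if (length(unique(labels[tr_idx])) >= 2) break
      }
      te_idx <- setdiff(seq_len(n), tr_idx)
      if (full) te_idx <- sample(te_idx)  # already n_test_full long
      tr <- feature_matrix(x[tr_idx, , drop = FALSE],
                           labels = labels[tr_idx], blocks = blocks)
      te <- feature_matrix(x[te_idx, , drop = FALSE], blocks = blocks)
      sc <- if (is.null(scaling)) fit_scaling(tr) else scaling
      model <- svm_train(apply_scaling(tr, sc), solver = solver,
                         cost_c = cost_c,
                         feature_condition = feature_condition)
      pred <- svm_predict(model, apply_scaling(te, sc))
      # test syllables of types absent from the training fold count as errors
      crs[r] <- correct_rate(pred$predicted_label, labels[te_idx])
    }
  })
  structure(list(
    condition = list(duration_s = duration_s,
                     corpus_duration_s = corpus_duration_s,
                     n_train = n_train, L = L, solver = solver,
                     feature_condition = feature_condition, cost_c = cost_c),
    correct_rates = crs,
    kappas = cohens_kappa(crs, L),
    summary = list(mean_cr = mean(crs), sd_cr = stats::sd(crs),
                   mean_kappa = mean(cohens_kappa(crs, L)))),
    class = "cv_result")
}
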