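# Whole-dataset accuracy estimation from evaluation scores: verify a small
# score-stratified subset by hand, fit a logistic correct-rate curve over
# the score axis, weight it by the score density, and integrate.

.DEFAULT_LOCATIONS <- seq(-0.8, 0.8, by = 0.2)

#' Select score-stratified verification subsets
#'
#' At each location on the evaluation-score axis (default
#' -0.8, -0.6, ..., 0.8 — spanning the two margins), up to
#' `max_per_location` samples nearest to the location and within
#' `location +- window` are selected for manual verification. Ties at the
#' cap are broken by sample index, so selection is deterministic.
#'
#' @param scores numeric evaluation scores (one per sample).
#' @param locations score locations (default `seq(-0.8, 0.8, 0.2)`).
#' @param window half-width of the selection window (default 0.1).
#' @param max_per_location cap per location (default 50).
#' @return List of `score_subset` objects (location, `sample_ids`,
#'   `scores`); empty subsets are kept and flagged with a message.
#' @export
select_subsets <- function(scores, locations = .DEFAULT_LOCATIONS,
                           window = 0.1, max_per_location = 50) {
  stopifnot(length(scores) > 0)
  out <- lapply(locations, function(loc) {
    ids <- which(abs(scores - loc) <= window + 1e-12)
    if (length(ids) > max_per_location) {
      d <- abs(scores[ids] - loc)
      ids <- ids[order(d, ids)][seq_len(max_per_location)]
      ids <- sort(ids)
    }
    structure(list(location = loc, sample_ids = ids, scores = scores[ids]),
              class = "score_subset")
  })
  n_empty <- sum(vapply(out, function(s) length(s$sample_ids) == 0, logical(1)))
  if (n_empty > 0)
    message(n_empty, " of ", length(locations),
            " score locations have no samples in range")
  out
}

#' Fit the correct-rate function over the evaluation-score axis
#'
#' Logistic regression of per-sample correctness on the evaluation score,
#' `CR(s) = 1 / (1 + exp(-(a + b s)))`, fitted by maximum likelihood on
#' the pooled verified samples. Under complete separation (e.g. every
#' verified sample correct) the fit falls back to a weakly penalised
#' likelihood (tiny split pseudo-observations at the score extremes) with
#' a warning; a fitted negative slope is also reported with a warning.
#'
#' @param subsets list of `score_subset` objects from [select_subsets()].
#' @param correctness logical (or 0/1) vector over all samples indexed by
#'   the subsets' `sample_ids` — from ground truth or manual verification.
#' @return Object of class `correct_rate_curve`: list with `a`, `b`, the
#'   pooled fitting data, and `predict(s)` via [predict_curve()].
#' @export
fit_correct_rate_curve <- function(subsets, correctness) {
  ids <- unlist(lapply(subsets, `[[`, "sample_ids"))
  sc <- unlist(lapply(subsets, `[[`, "scores"))
  if (length(ids) == 0) stop("no verified samples in any subset")
  ok <- as.numeric(correctness[ids])
  if (anyNA(ok)) stop("correctness missing for some selected samples")
  n_loc <- sum(vapply(subsets, function(s) length(s$sample_ids) > 0, logical(1)))
  if (n_loc < 2) stop("need samples at two or more score locations")

  fit_glm <- function(s, y, w) suppressWarnings(
    stats::glm(y ~ s, family = stats::binomial(), weights = w))

  separated <- length(unique(ok)) < 2
  fit <- NULL
  if (!separated) {
    fit <- withCallingHandlers(
      stats::glm(ok ~ sc, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (max(abs(stats::coef(fit))) > 1e3) separated <- TRUE
  }
  if (separated) {
    warning("separation in the logistic fit; using a weakly penalised fit")
    # split pseudo-observations at the score extremes shrink |b| to finite
    s_aug <- c(sc, range(sc), range(sc))
    y_aug <- c(ok, 0, 0, 1, 1)
    w_aug <- c(rep(1, length(ok)), rep(0.05, 4))
    fit <- fit_glm(s_aug, y_aug, w_aug)
  }
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (b < 0) warning("fitted correct-rate curve has negative slope (b = ",
                     signif(b, 3), ")")
  structure(list(a = a, b = b, scores = sc, correctness = ok,
                 n_verified = length(ok)),
            class = "correct_rate_curve")
}

#' Evaluate a fitted correct-rate curve
#'
#' @param curve a `correct_rate_curve`.
#' @param s score values.
#' @return `CR(s) = plogis(a + b s)`.
#' @export
predict_curve <- function(curve, s) {
  stopifnot(inherits(curve, "correct_rate_curve"))
  stats::plogis(curve$a + curve$b * s)
}

#' Occurrence probability density of evaluation scores
#'
#' Each source (bird/recording) contributes a proportional histogram (bin
#' width `bin`, each summing to one); histograms are averaged across
#' sources — so small and large sources weigh equally — and smoothed with
#' a Gaussian kernel into a density integrating to 1 on a fixed grid over
#' `[min(scores) - 1, max(scores) + 1]` with step 0.01.
#'
#' @param scores numeric evaluation scores.
#' @param source optional per-sample grouping (defaults to one source).
#' @param bin histogram bin width (default 0.1).
#' @param bandwidth Gaussian smoothing bandwidth (default 0.15).
#' @return Object of class `score_density`: list with `s` (grid),
#'   `density`, and the per-source averaged histogram.
#' @export
score_density <- function(scores, source = NULL, bin = 0.1,
                          bandwidth = 0.15) {
  stopifnot(length(scores) > 0)
  if (is.null(source)) source <- rep("all", length(scores))
  stopifnot(length(source) == length(scores))

  lo <- floor(min(scores) / bin) * bin - bin / 2
  hi <- ceiling(max(scores) / bin) * bin + bin / 2
  breaks <- seq(lo, hi + bin, by = bin)
  centers <- breaks[-length(breaks)] + bin / 2
  groups <- split(scores, source)
  props <- vapply(groups, function(g) {
    h <- tabulate(findInterval(g, breaks, rightmost.closed = TRUE),
                  nbins = length(centers))
    h / sum(h)
  }, numeric(length(centers)))
  mean_prop <- if (is.matrix(props)) rowMeans(props) else props

  s <- seq(min(scores) - 1, max(scores) + 1, by = 0.01)
  dens <- numeric(length(s))
  for (i in seq_along(centers)) {
    if (mean_prop[i] > 0)
      dens <- dens + mean_prop[i] * stats::dnorm(s, centers[i], bandwidth)
  }
  area <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(s))
  dens <- dens / area
  structure(list(s = s, density = dens, centers = centers,
                 mean_proportions = mean_prop),
            class = "score_density")
}

#' Estimate the overall correct rate of a large dataset
#'
#' Multiplies the fitted correct-rate function by the occurrence
#' probability density of the evaluation score to obtain the probability
#' density of correct labels, and integrates it (trapezoidal rule) to give
#' the overall correct rate. The cumulative curve is accumulated from high
#' to low score, showing how the estimate converges as ever less confident
#' syllables are included.
#'
#' @param curve a `correct_rate_curve`.
#' @param density a `score_density`.
#' @return Object of class `accuracy_estimate`: list with `s`,
#'   `score_density`, `correct_density`, `overall_correct_rate`, and
#'   `cumulative` (running integral from high to low score, reported on
#'   the same grid).
#' @export
estimate_overall <- function(curve, density) {
  stopifnot(inherits(curve, "correct_rate_curve"),
            inherits(density, "score_density"))
  s <- density$s
  p <- density$density
  cr <- predict_curve(curve, s)
  cd <- cr * p
  ds <- diff(s)
  trap <- (cd[-1] + cd[-length(cd)]) / 2 * ds
  overall <- sum(trap)
  # accumulate from plus to minus on the score axis
  cum_rev <- rev(cumsum(rev(c(trap, 0))))
  structure(list(s = s, score_density = p, correct_rate = cr,
                 correct_density = cd,
                 overall_correct_rate = overall,
                 cumulative = cum_rev,
                 curve = curve),
            class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("<accuracy_estimate> overall correct rate %.2f%% (logistic a = %.3f, b = %.3f)\n",
              100 * x$overall_correct_rate, x$curve$a, x$curve$b))
  invisible(x)
}

#' Plot an accuracy estimate
#'
#' Three panels: score density, the fitted correct-rate curve, and the
#' cumulative correct-rate estimate accumulated from high to low scores.
#'
#' @param x an `accuracy_estimate`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.accuracy_estimate <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$s, x$score_density, type = "l", xlab = "evaluation score",
                 ylab = "density", ...)
  graphics::plot(x$s, x$correct_rate, type = "l", ylim = c(0, 1),
                 xlab = "evaluation score", ylab = "correct rate")
  graphics::plot(x$s, x$cumulative, type = "l",
                 xlab = "evaluation score",
                 ylab = "cumulative correct rate")
  graphics::abline(h = x$overall_correct_rate, lty = 2)
  invisible(x)
}

#' Retention analysis for a rejection threshold
#'
#' For a candidate rejection threshold on the evaluation-score axis:
#' the fraction of all syllables that would be retained (density mass
#' above the threshold) and the density-weighted mean correct rate among
#' them. Raising the threshold trades coverage for labeling reliability.
#'
#' @param curve a `correct_rate_curve`.
#' @param density a `score_density`.
#' @param threshold rejection threshold.
#' @return List with `fraction_retained` and `cr_among_retained` (`NA`
#'   when nothing is retained).
#' @export
retention_analysis <- function(curve, density, threshold) {
  s <- density$s
  keep <- s >= threshold
  if (sum(keep) < 2)
    return(list(fraction_retained = 0, cr_among_retained = NA_real_))
  sk <- s[keep]; pk <- density$density[keep]
  crk <- predict_curve(curve, sk)
  ds <- diff(sk)
  mass <- sum((pk[-1] + pk[-length(pk)]) / 2 * ds)
  num <- sum(((crk * pk)[-1] + (crk * pk)[-length(pk)]) / 2 * ds)
  list(fraction_retained = mass,
       cr_among_retained = if (mass > 0) num / mass else NA_real_)
}
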