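#' Fit blockwise z-standardisation factors
#'
#' The spectrum, delta-spectrum, cepstrum, and delta-cepstrum blocks are
#' standardised with a single pooled mean and SD per block (standardising
#' each coefficient separately would destroy covariance structure among the
#' coefficients); the 20 summary acoustic features are standardised
#' per column. Factors fitted on training data are reused verbatim on test
#' data.
#'
#' @param m a `feature_matrix` with at least 2 rows.
#' @return Object of class `scaling_factors`: list with `pooled` (per-block
#'   mean/sd) and `columns` (per-column mean/sd for non-pooled blocks), plus
#'   the block layout.
#' @export
fit_scaling <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (nrow(m) < 2) stop("need at least 2 samples to fit scaling factors")
  blocks <- attr(m, "blocks")
  x <- unclass(m)
  pooled <- list(); columns <- list()
  for (b in names(blocks)) {
    cols <- blocks[[b]]
    if (b == "af") {
      mu <- colMeans(x[, cols, drop = FALSE])
      sdv <- apply(x[, cols, drop = FALSE], 2, stats::sd)
      const <- sdv < 1e-12
      if (any(const)) {
        warning(sum(const), " constant AF column(s); mapped to 0 after scaling")
        sdv[const] <- 1
      }
      columns[[b]] <- list(mean = mu, sd = sdv)
    } else {
      v <- as.numeric(x[, cols, drop = FALSE])
      mu <- mean(v); sdv <- stats::sd(v)
      if (sdv < 1e-12) { warning("constant block ", b); sdv <- 1 }
      pooled[[b]] <- list(mean = mu, sd = sdv)
    }
  }
  structure(list(pooled = pooled, columns = columns, blocks = blocks),
            class = "scaling_factors")
}

#' Apply previously fitted scaling factors
#'
#' @param m a `feature_matrix` with the same block structure the factors
#'   were fitted on.
#' @param s a `scaling_factors` object (no refitting takes place).
#' @return The standardised `feature_matrix`.
#' @export
apply_scaling <- function(m, s) {
  stopifnot(inherits(m, "feature_matrix"), inherits(s, "scaling_factors"))
  blocks <- attr(m, "blocks")
  if (!identical(lapply(blocks, length), lapply(s$blocks, length)))
    stop("block structure of matrix and scaling factors differ")
  x <- unclass(m)
  for (b in names(blocks)) {
    cols <- blocks[[b]]
    if (!is.null(s$columns[[b]])) {
      x[, cols] <- sweep(sweep(x[, cols, drop = FALSE], 2,
                               s$columns[[b]]$mean), 2, s$columns[[b]]$sd, "/")
    } else {
      x[, cols] <- (x[, cols] - s$pooled[[b]]$mean) / s$pooled[[b]]$sd
    }
  }
  feature_matrix(x, labels = attr(m, "labels"), blocks = blocks)
}

.SOLVERS <- c("2R-2L", "2R-1L", "1R-2L")

#' Train a linear soft-margin multiclass SVM
#'
#' One-vs-rest linear SVMs, one weight vector and bias per class, under one
#' of three regularisation/loss combinations: `"2R-2L"` (L2-regularised
#' squared hinge, the default), `"2R-1L"` (L2-regularised hinge), or
#' `"1R-2L"` (L1-regularised squared hinge). The soft-margin cost is fixed
#' at 1 by default; classification accuracy is flat over many orders of
#' magnitude of the cost on separable song data. The bias is handled by
#' unit augmentation and training is deterministic (internally seeded
#' coordinate descent).
#'
#' @param m a standardised `feature_matrix`.
#' @param labels class label per row (defaults to the matrix's `labels`
#'   attribute). At least two classes required.
#' @param solver one of `"2R-2L"`, `"2R-1L"`, `"1R-2L"`.
#' @param cost_c soft-margin cost parameter (default 1).
#' @param tol solver stopping tolerance (default 1e-4).
#' @param max_iter maximum solver iterations (default 10000).
#' @param scaling optional `scaling_factors` to store with the model.
#' @param feature_condition descriptor of the columns in `m`
#'   (default `"ALL"`).
#' @return Object of class `svm_model`: list with `labels` (class order),
#'   `weights` (d x K matrix), `bias` (length K), `solver`, `cost_c`,
#'   `scaling`, `feature_condition`.
#' @export
svm_train <- function(m, labels = attr(m, "labels"), solver = "2R-2L",
                      cost_c = 1, tol = 1e-4, max_iter = 10000,
                      scaling = NULL, feature_condition = "ALL") {
  solver <- match.arg(solver, .SOLVERS)
  x <- unclass(as.matrix(m))
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite feature values")
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels length must match row count")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")

  xa <- cbind(x, 1)  # unit augmentation carries the bias
  d <- ncol(xa)
  W <- matrix(0, nrow = d, ncol = length(classes))
  for (k in seq_along(classes)) {
    y <- ifelse(labels == classes[k], 1, -1)
    W[, k] <- switch(solver,
      "2R-2L" = .svm_l2r_dual(xa, y, cost_c, TRUE, tol, max_iter, 0L),
      "2R-1L" = .svm_l2r_dual(xa, y, cost_c, FALSE, tol, max_iter, 0L),
      "1R-2L" = .svm_l1r_l2l(xa, y, cost_c, tol, max_iter, 0L))
  }
  structure(list(labels = classes,
                 weights = W[-d, , drop = FALSE],
                 bias = W[d, ],
                 solver = solver, cost_c = cost_c,
                 scaling = scaling, feature_condition = feature_condition,
                 pca = NULL),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d classes (%s), solver %s, c = %g, %d features\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$solver, x$cost_c, nrow(x$weights)))
  invisible(x)
}

#' Classify syllables and compute evaluation scores
#'
#' Each sample is projected on every class's evaluation axis (decision
#' value `w_k . x + b_k`; class boundary at 0, margins at +-1) and assigned
#' to the class with the highest value. The evaluation score of a sample is
#' that maximum decision value — a confidence index that is low when the
#' sample resembles no trained class.
#'
#' @param model an `svm_model`.
#' @param m a `feature_matrix`, already standardised with the same factors
#'   as the training data (see [apply_scaling()]).
#' @return A data frame with `predicted_label`, `evaluation_score`, and one
#'   `score.<class>` column of decision values per class.
#' @export
svm_predict <- function(model, m) {
  stopifnot(inherits(model, "svm_model"))
  x <- unclass(as.matrix(m))
  if (ncol(x) != nrow(model$weights))
    stop("feature dimension (", ncol(x), ") does not match model (",
         nrow(model$weights), ")")
  dv <- x %*% model$weights + matrix(model$bias, nrow(x), ncol(model$weights),
                                     byrow = TRUE)
  colnames(dv) <- model$labels
  best <- max.col(dv, ties.method = "first")
  out <- data.frame(predicted_label = model$labels[best],
                    evaluation_score = dv[cbind(seq_len(nrow(dv)), best)],
                    stringsAsFactors = FALSE)
  dvd <- as.data.frame(dv)
  names(dvd) <- paste0("score.", model$labels)
  cbind(out, dvd)
}

#' Classify with rejection of unreliable syllables
#'
#' Samples whose evaluation score falls below `reject_below` are labeled
#' `"unknown"` instead of their argmax class, excluding unreliable
#' syllables from downstream analysis.
#'
#' @inheritParams svm_predict
#' @param reject_below rejection threshold on the evaluation-score axis.
#' @return As [svm_predict()], with rejected rows labeled `"unknown"`.
#' @export
predict_with_rejection <- function(model, m, reject_below) {
  stopifnot(is.finite(reject_below) || is.infinite(reject_below))
  p <- svm_predict(model, m)
  p$predicted_label[p$evaluation_score < reject_below] <- "unknown"
  p
}

#' Reduce train and test features by principal components
#'
#' Components are fitted on the (already standardised) training matrix
#' only; the test matrix is projected with the training loadings and
#' centers.
#'
#' @param train,test standardised `feature_matrix` objects with matching
#'   columns.
#' @param n_components number of leading components to keep.
#' @return List with reduced `train` and `test` feature matrices (block
#'   `pc`) and the `prcomp` fit (`rotation`).
#' @export
pca_reduce <- function(train, test, n_components) {
  stopifnot(ncol(train) == ncol(test))
  if (n_components > min(nrow(train) - 1, ncol(train)))
    stop("n_components exceeds the rank of the training data")
  pc <- stats::prcomp(unclass(as.matrix(train)), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  proj <- function(m) sweep(unclass(as.matrix(m)), 2, pc$center) %*% rot
  mk <- function(z, src) feature_matrix(z, labels = attr(src, "labels"),
                                        blocks = list(pc = seq_len(ncol(z))))
  list(train = mk(proj(train), train), test = mk(proj(test), test),
       rotation = rot, center = pc$center)
}

#' Save a trained model as a JSON document
#'
#' Stores the label map, solver, cost, per-class weights and biases,
#' scaling factors, and feature condition at full double precision, so a
#' reloaded model reproduces predictions bit for bit.
#'
#' @param model an `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  doc <- list(
    format = "songsvm-model-1",
    labels = model$labels,
    solver = model$solver,
    cost_c = model$cost_c,
    feature_condition = model$feature_condition,
    weights = unname(apply(model$weights, 2, as.numeric, simplify = FALSE)),
    bias = as.numeric(model$bias),
    scaling = if (is.null(model$scaling)) NULL else list(
      blocks = lapply(model$scaling$blocks, as.integer),
      pooled = model$scaling$pooled,
      columns = model$scaling$columns))
  # I(17) significant digits: IEEE doubles survive the text round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path path to the JSON model document.
#' @return An `svm_model`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "songsvm-model-1"))
    stop("not a songsvm model file: ", path)
  W <- if (is.matrix(doc$weights)) t(doc$weights)   # K x d when simplified
       else do.call(cbind, lapply(doc$weights, as.numeric))
  scaling <- NULL
  if (!is.null(doc$scaling)) {
    scaling <- structure(list(
      pooled = lapply(doc$scaling$pooled, function(p)
        list(mean = p$mean, sd = p$sd)),
      columns = lapply(doc$scaling$columns, function(p)
        list(mean = unlist(p$mean), sd = unlist(p$sd))),
      blocks = lapply(doc$scaling$blocks, as.integer)),
      class = "scaling_factors")
  }
  structure(list(labels = doc$labels, weights = W, bias = as.numeric(doc$bias),
                 solver = doc$solver, cost_c = doc$cost_c, scaling = scaling,
                 feature_condition = doc$feature_condition, pca = NULL),
            class = "svm_model")
}
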