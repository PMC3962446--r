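test_that("blockwise standardisation pools the four 128-blocks", {
  pool <- clean_pool()
  s <- fit_scaling(pool)
  z <- apply_scaling(pool, s)
  b <- attr(z, "blocks")
  for (blk in c("spec", "dspec", "ceps", "dceps")) {
    v <- as.numeric(unclass(z)[, b[[blk]]])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(stats::sd(v) - 1), 1e-6)
  }
  af <- unclass(z)[, b$af]
  expect_true(all(abs(colMeans(af)) < 1e-9))
  expect_true(all(abs(apply(af, 2, stats::sd) - 1) < 1e-6))
})

test_that("train-fitted factors are reused verbatim on test data", {
  pool <- clean_pool()
  x <- unclass(pool)
  tr <- feature_matrix(x[1:50, ], labels = attr(pool, "labels")[1:50])
  te <- feature_matrix(x[51:80, ])
  s <- fit_scaling(tr)
  zte <- apply_scaling(te, s)
  # test-set blocks are NOT zero-mean under the training factors
  v <- as.numeric(unclass(zte)[, 1:128])
  expect_gt(abs(mean(v)), 1e-6)
  # identity factors leave the matrix unchanged
  ident <- s
  for (b in names(ident$pooled)) ident$pooled[[b]] <- list(mean = 0, sd = 1)
  ident$columns$af <- list(mean = rep(0, 20), sd = rep(1, 20))
  expect_equal(unclass(apply_scaling(te, ident)), unclass(te))
})

test_that("constant columns trigger the SD guard and map to zero", {
  x <- matrix(rnorm(40), 10, 4)
  x[, 2] <- 5
  fm <- feature_matrix(x, blocks = list(af = 1:4))
  expect_warning(s <- fit_scaling(fm), "constant")
  z <- apply_scaling(fm, s)
  expect_true(all(unclass(z)[, 2] == 0))
})

test_that("decision values realise the soft-margin geometry", {
  fm <- toy_clouds()
  model <- svm_train(fm, cost_c = 100)
  pred <- svm_predict(model, fm)
  dv <- as.matrix(pred[, c("score.a", "score.b")])
  # functional margins +-1 at the class edges, boundary at 0
  expect_equal(min(abs(dv)), 1, tolerance = 0.05)
  # points far inside their class score above the margin
  expect_gt(mean(pred$evaluation_score > 1), 0.9)
  # argmax/evaluation-score consistency
  expect_equal(pred$evaluation_score, apply(dv, 1, max))
  expect_equal(pred$predicted_label,
               c("a", "b")[max.col(dv, ties.method = "first")])
})

test_that("all three solvers separate and agree with an independent SVM", {
  fm <- toy_clouds()
  labs <- attr(fm, "labels")
  for (solver in c("2R-2L", "2R-1L", "1R-2L")) {
    model <- svm_train(fm, solver = solver)
    pred <- svm_predict(model, fm)
    expect_equal(correct_rate(pred$predicted_label, labs), 1)
  }
  skip_if_not_installed("e1071")
  ref <- e1071::svm(unclass(fm), factor(labs), kernel = "linear",
                    cost = 100, scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  own <- svm_train(fm, solver = "2R-1L", cost_c = 100)
  w_own <- own$weights[, 1] / sqrt(sum(own$weights[, 1]^2))
  expect_lt(max(abs(abs(w_own) - abs(w_ref))), 0.02)
})

test_that("training is deterministic and cost-insensitive on separable data", {
  fm <- toy_clouds()
  m1 <- svm_train(fm); m2 <- svm_train(fm)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-6)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-6)
  labs <- attr(fm, "labels")
  acc <- vapply(c(0.01, 1, 1e4), function(cc) {
    p <- svm_predict(svm_train(fm, cost_c = cc), fm)
    correct_rate(p$predicted_label, labs)
  }, numeric(1))
  expect_lt(max(acc) - min(acc), 0.01)
})

test_that("degenerate training inputs are rejected", {
  fm <- toy_clouds()
  one <- feature_matrix(unclass(fm)[1:50, ], labels = rep("a", 50),
                        blocks = list(x = 1:2))
  expect_error(svm_train(one), "2 classes")
  bad <- unclass(fm); bad[1, 1] <- NA
  expect_error(svm_train(feature_matrix(bad, labels = attr(fm, "labels"),
                                        blocks = list(x = 1:2))),
               "non-finite")
})

test_that("rejection thresholding labels low-score syllables unknown", {
  fm <- toy_clouds()
  model <- svm_train(fm)
  p0 <- predict_with_rejection(model, fm, -Inf)
  expect_equal(p0$predicted_label, svm_predict(model, fm)$predicted_label)
  p1 <- predict_with_rejection(model, fm, Inf)
  expect_true(all(p1$predicted_label == "unknown"))
  # retained-sample correct rate never decreases as the threshold rises
  set.seed(12)
  noisy <- feature_matrix(unclass(fm) + matrix(rnorm(200, 0, 1.2), 100, 2),
                          labels = attr(fm, "labels"), blocks = list(x = 1:2))
  labs <- attr(fm, "labels")
  crs <- vapply(seq(-1, 1, by = 0.5), function(th) {
    p <- predict_with_rejection(model, noisy, th)
    keep <- p$predicted_label != "unknown"
    if (!any(keep)) NA_real_ else correct_rate(p$predicted_label[keep], labs[keep])
  }, numeric(1))
  crs <- crs[!is.na(crs)]
  expect_true(all(diff(crs) >= -1e-9))
})

test_that("PCA projection uses training loadings and reconstructs at full rank", {
  pool <- clean_pool()
  s <- fit_scaling(pool)
  z <- apply_scaling(pool, s)
  x <- unclass(z)
  tr <- feature_matrix(x[1:60, ], labels = attr(pool, "labels")[1:60])
  te <- feature_matrix(x[61:90, ])
  k <- 59  # rank of the 60-sample training set
  red <- pca_reduce(tr, te, k)
  recon <- unclass(red$train) %*% t(red$rotation) +
    matrix(red$center, 60, 532, byrow = TRUE)
  expect_equal(recon, x[1:60, ], tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(pca_reduce(tr, te, 60), "rank")
  # projecting test data must not refit: a shifted test set shifts scores
  te2 <- feature_matrix(x[61:90, ] + 1)
  red2 <- pca_reduce(tr, te2, 10)
  expect_false(isTRUE(all.equal(unclass(red2$test), unclass(red$test))))
})

test_that("the seven feature conditions select the documented column counts", {
  pool <- clean_pool()
  widths <- c("Spec" = 256, "Ceps" = 256, "AF" = 20, "Spec+Ceps" = 512,
              "Spec+AF" = 276, "Ceps+AF" = 276, "ALL" = 532)
  for (cond in names(widths)) {
    sel <- select_feature_condition(pool, cond)
    expect_equal(ncol(sel), unname(widths[cond]))
  }
  expect_equal(colnames(select_feature_condition(pool, "Ceps+AF"))[1], "ceps.001")
})

test_that("models round-trip through JSON with bit-identical predictions", {
  pool <- clean_pool()
  s <- fit_scaling(pool)
  z <- apply_scaling(pool, s)
  model <- svm_train(z, scaling = s)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  model2 <- load_model(path)
  p1 <- svm_predict(model, z)
  p2 <- svm_predict(model2, z)
  expect_identical(p1$evaluation_score, p2$evaluation_score)
  expect_identical(p1$predicted_label, p2$predicted_label)
})
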