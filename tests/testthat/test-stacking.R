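test_that("stratified folds balance both classes", {
  y <- c(rep(1, 23), rep(0, 31))
  fold <- stratified_folds(y, 5, seed = 3)
  for (cls in c(0, 1)) {
    sizes <- table(fold[y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(stratified_folds(c(1, 1, 1, 0), 3), "cannot stratify")
})

test_that("label-oracle stubs validate the out-of-fold plumbing", {
  w <- random_windows(20, seed = 14)
  y <- rep(c(1, 0), 10)
  specs <- list(stub_model_spec(w, y, "oracle_a"),
                stub_model_spec(w, y, "oracle_b"),
                stub_model_spec(w, y, "oracle_c"))
  oof <- oof_predictions(specs, w, y, k_folds = 5, seed = 2)
  # the stub returns the true label, so every column equals y exactly
  expect_equal(unname(oof$values), matrix(y, 20, 3))
  expect_true(all(oof$values >= 0 & oof$values <= 1))
  # leakage audit: sample i is never in the training set of its own fold model
  for (i in seq_along(w)) {
    expect_false(i %in% oof$train_index_log[[oof$fold[i]]])
  }
  # every sample predicted exactly once per architecture
  expect_false(anyNA(oof$values))
  # determinism
  oof2 <- oof_predictions(specs, w, y, k_folds = 5, seed = 2)
  expect_identical(oof$values, oof2$values)
  expect_identical(oof$fold, oof2$fold)
})

test_that("meta features are [base probs, flattened one-hot] at width 167", {
  w <- random_windows(10, L = 41, seed = 15)
  probs <- matrix(runif(30), 10, 3)
  X_flat <- encode_windows(w, "onehot", flatten = TRUE)
  Z <- assemble_meta_features(probs, X_flat)
  expect_identical(dim(Z), c(10L, 167L))
  expect_equal(unname(Z[, 1:3]), probs)
  expect_equal(unname(Z[, -(1:3)]), unname(X_flat))
  # degenerate ablation: no original features
  expect_identical(ncol(assemble_meta_features(probs,
                                               matrix(0, 10, 0))), 3L)
  expect_error(assemble_meta_features(probs, X_flat[1:5, ]), "mismatch")
})

test_that("meta-learner solves separable and degenerate problems", {
  set.seed(16)
  n <- 200
  y <- rep(c(1, 0), n / 2)
  Z <- cbind(y, matrix(rnorm(n * 5), n, 5))  # column 1 is the label
  tr <- 1:150; te <- 151:200
  m <- fit_meta(Z[tr, ], y[tr])
  expect_true(m$converged)
  acc <- mean((predict_meta(m, Z[te, ]) >= 0.5) == y[te])
  expect_gte(acc, 0.95)

  # all-constant features: prediction collapses to the class prior
  y2 <- c(rep(1, 30), rep(0, 70))
  Zc <- matrix(1, 100, 3)
  m2 <- fit_meta(Zc, y2)
  expect_equal(unname(predict_meta(m2, Zc)), rep(0.3, 100), tolerance = 1e-4)

  # duplicating every row leaves the decision direction unchanged
  m3 <- fit_meta(rbind(Z[tr, ], Z[tr, ]), c(y[tr], y[tr]))
  cosine <- sum(m$weights * m3$weights) /
    sqrt(sum(m$weights^2) * sum(m3$weights^2))
  expect_gt(cosine, 0.999)

  expect_error(fit_meta(Z, rep(1, n)), "both classes")
})

test_that("stub ensemble reaches 100% training accuracy through the plumbing", {
  w <- random_windows(30, seed = 17)
  y <- rep(c(1, 0), 15)
  specs <- lapply(c("a", "b", "c"),
                  function(nm) stub_model_spec(w, y, nm))
  ens <- fit_stacked_ensemble(specs, w, y, k_folds = 5, seed = 3)
  expect_identical(ens$feature_recipe$meta_width, 167L)
  p <- predict_ensemble(ens, w)
  expect_identical(mean((p >= 0.5) == y), 1)
  # monotone response under positive meta weights on the base columns
  w_base <- ens$meta_model$weights[1:3]
  expect_true(all(w_base > 0))
  Z <- assemble_meta_features(matrix(0.2, 1, 3),
                              encode_windows(w[1], "onehot", flatten = TRUE))
  Z_hi <- Z; Z_hi[1, 1:3] <- 0.9
  expect_gte(predict_meta(ens$meta_model, Z_hi),
             predict_meta(ens$meta_model, Z))
})

test_that("real ensemble round-trips through save/load", {
  ds <- strong_dataset(20, 20, seed = 18)
  specs <- list(tiny_spec("dcnn_bilstm"))
  ens <- fit_stacked_ensemble(specs, ds, k_folds = 2,
                              config = fast_cfg(1, seed = 4), seed = 4)
  w_new <- random_windows(8, seed = 19)
  p_before <- predict_ensemble(ens, w_new)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "ensemble.json")))
  ens2 <- load_ensemble(dir)
  expect_equal(predict_ensemble(ens2, w_new), p_before, tolerance = 1e-8)
  expect_identical(ens2$feature_recipe$meta_width, 165L)  # 1 + 41*4
  # batch-of-one consistency at the ensemble level
  expect_equal(predict_ensemble(ens, w_new[2]), p_before[2],
               tolerance = 1e-10)
})

test_that("stacking does no harm on strongly separable data", {
  train <- strong_dataset(500, 500, seed = 20, effect = 1)
  test <- strong_dataset(500, 500, seed = 21, effect = 1)
  y_te <- dataset_labels(test)
  specs <- list(base_model_spec("densenet_senet"),
                base_model_spec("dcnn_bilstm"),
                base_model_spec("msrn_bigru"))
  cfg <- train_config(epochs = 2, batch_size = 64, learning_rate = 2e-3,
                      early_stopping_patience = 2, dropout_rate = 0.2,
                      seed = 5)
  ens <- fit_stacked_ensemble(specs, train, k_folds = 2, config = cfg,
                              seed = 5)
  auc_ens <- auroc(y_te, predict_ensemble(ens, test))
  auc_base <- vapply(ens$base_models,
                     function(m) auroc(y_te, predict_proba(m, test)),
                     numeric(1))
  expect_gte(auc_ens, max(auc_base) - 0.02)
})
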