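brute_dilated_conv <- function(x, w, b, k) {
  N <- length(w)
  n_out <- length(x) - k * N + 1
  if (n_out < 1) return(numeric(0))
  out <- numeric(n_out)
  for (i in 0:(n_out - 1)) {
    acc <- b
    for (n in seq_len(N)) acc <- acc + x[i + k * n] * w[n]
    out[i + 1] <- acc
  }
  out
}

test_that("dilated_conv1d matches the index-arithmetic oracle", {
  # worked example: each output is x_{i+2} + x_{i+4}
  expect_equal(dilated_conv1d(1:6, c(1, 1), dilation = 2), c(6, 8, 10))
  # zero weights and bias give the zero map under f(0) = 0 activations
  expect_equal(dilated_conv1d(rnorm(10), c(0, 0, 0), 0, 2), rep(0, 5))
  set.seed(21)
  for (rep in 1:30) {
    x <- rnorm(sample(8:20, 1))
    w <- rnorm(sample(2:4, 1))
    b <- rnorm(1)
    for (k in 1:3) {
      expect_equal(dilated_conv1d(x, w, b, k), brute_dilated_conv(x, w, b, k))
    }
  }
})

test_that("dilation 1 reproduces a standard valid convolution", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(15); w <- rnorm(3)
    direct <- vapply(1:13, function(j) sum(x[j:(j + 2)] * w), numeric(1))
    expect_equal(dilated_conv1d(x, w, 0, 1), direct)
  }
})

test_that("dense block realizes X(X+1)/2 connections and grows channels", {
  for (X in 1:6) {
    db <- dense_block_forward(matrix(rnorm(20), 5, 4), X,
                              transform = function(n) n)
    expect_identical(db$n_connections, as.integer(X * (X + 1) / 2))
  }
  # with a 1-channel H on a 1-channel input, state width after layer i is i+1
  db <- dense_block_forward(matrix(1, 5, 1), 4, transform = function(n) {
    m6AmStack:::ag_slice_cols(n, 1L)
  })
  expect_identical(db$channel_history, 2:5)
})

test_that("SE block honours forced gates and the residual modification", {
  set.seed(23)
  x <- matrix(rnorm(28), 7, 4)
  # gates forced to 0: residual form returns the input unchanged
  expect_equal(se_block_apply(x, gate_override = 0)$output, x)
  # gates saturated at 1: x + 1*x = 2x
  expect_equal(se_block_apply(x, gate_override = 1)$output, 2 * x)
  # without the residual, zero gates give the zero map
  expect_equal(se_block_apply(x, gate_override = 0,
                              residual = FALSE)$output, 0 * x)
  # squeeze of a constant channel is that constant
  xc <- cbind(x[, 1:3], 3.5)
  expect_equal(unname(se_block_apply(xc)$squeeze[4]), 3.5)
  # gates always in (0, 1)
  g <- se_block_apply(x, params = NULL)$gates
  expect_true(all(g > 0 & g < 1))
})

test_that("built models expose the mandated structural constants", {
  dn <- build_model(base_model_spec("densenet_senet"))
  expect_identical(dn$structure_info$n_dense_blocks, 6L)
  expect_identical(dn$structure_info$n_se_blocks_after_dense, 6L)
  expect_true(dn$structure_info$input_attention)
  expect_length(dn$params$blocks, 6L)

  dc <- build_model(base_model_spec("dcnn_bilstm"))
  expect_identical(dc$structure_info$dilation_rates, c(1L, 2L, 3L))
  expect_length(dc$params$branches, 3L)

  ms <- build_model(base_model_spec("msrn_bigru"))
  expect_identical(ms$structure_info$n_msrb, 6L)
  expect_identical(ms$structure_info$convs_per_block, 3L)
  expect_identical(ms$structure_info$kernels_per_layer, 64L)
  expect_identical(ms$structure_info$fusion_filters, 192L)
  expect_length(ms$params$blocks, 6L)
  # 64 kernels per in-block convolution, 192 fusion filters, by inspection
  expect_identical(ncol(ms$params$blocks[[1]]$conv_a$W$value), 64L)
  expect_identical(ncol(ms$params$blocks[[1]]$conv_b$W$value), 64L)
  expect_identical(ncol(ms$params$blocks[[1]]$fuse$W$value), 64L)
  expect_identical(ncol(ms$params$fusion$W$value), 192L)
})

test_that("untrained models map batches to probabilities in [0, 1]", {
  w <- random_windows(6, seed = 11)
  for (arch in c("densenet_senet", "dcnn_bilstm", "msrn_bigru")) {
    m <- build_model(tiny_spec(arch), seed = 2)
    p <- predict_proba(m, w)
    expect_length(p, 6L)
    expect_true(all(p >= 0 & p <= 1))
    # pure function of the input: duplicated window, identical probability
    p2 <- predict_proba(m, c(w[1], w[1]))
    expect_equal(p2[1], p2[2])
    # batch-of-one equals the corresponding full-batch entry
    expect_equal(predict_proba(m, w[3]), p[3], tolerance = 1e-10)
    expect_identical(predict_proba(m, character(0)), numeric(0))
  }
  expect_error(predict_proba(build_model(tiny_spec("dcnn_bilstm")),
                             "ACGU"), "length")
  expect_error(base_model_spec("vgg16"))
})

test_that("training is deterministic and rejects degenerate labels", {
  ds <- strong_dataset(15, 15, seed = 4)
  spec <- tiny_spec("dcnn_bilstm")
  m1 <- train_base_model(build_model(spec), ds, config = fast_cfg(2, seed = 9))
  m2 <- train_base_model(build_model(spec), ds, config = fast_cfg(2, seed = 9))
  w <- random_windows(10, seed = 12)
  expect_identical(predict_proba(m1, w), predict_proba(m2, w))
  expect_identical(m1$training_meta$seed, 9L)
  expect_identical(m1$training_meta$epochs_run, 2L)
  expect_true(is.finite(m1$training_meta$final_train_loss))

  expect_error(train_base_model(build_model(spec), rep(ds$window[1], 4),
                                rep(1, 4), fast_cfg()), "both classes")
})

test_that("each architecture learns a strongly separable problem quickly", {
  ds <- strong_dataset(100, 100, seed = 3)
  y <- dataset_labels(ds)
  cfg <- train_config(epochs = 5, batch_size = 16, learning_rate = 3e-3,
                      early_stopping_patience = 50, dropout_rate = 0.3,
                      seed = 5)
  for (arch in c("densenet_senet", "dcnn_bilstm", "msrn_bigru")) {
    m <- train_base_model(build_model(base_model_spec(arch)), ds, y, cfg)
    p <- predict_proba(m, ds)
    expect_gt(mean((p >= 0.5) == y), 0.9)
    expect_gt(mean(p[y == 1]), mean(p[y == 0]))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("shuffled labels give chance-level held-out AUROC", {
  ds <- strong_dataset(80, 80, seed = 6)
  y <- dataset_labels(ds)
  set.seed(7)
  y_shuf <- sample(y)
  m <- train_base_model(build_model(tiny_spec("dcnn_bilstm")), ds, y_shuf,
                        fast_cfg(3, seed = 8))
  held <- strong_dataset(100, 100, seed = 60)
  a <- auroc(dataset_labels(held), predict_proba(m, held))
  expect_gt(a, 0.4)
  expect_lt(a, 0.6)
})

test_that("one training step moves parameters in every sub-block", {
  ns <- asNamespace("m6AmStack")
  ds <- strong_dataset(8, 8, seed = 9)
  for (arch in c("densenet_senet", "dcnn_bilstm", "msrn_bigru")) {
    m <- train_base_model(build_model(tiny_spec(arch)), ds,
                          config = fast_cfg(1, batch_size = 16, seed = 3))
    ref <- build_model(tiny_spec(arch), seed = 3)  # same init as training
    after <- ns$flatten_params(m$params)
    before <- ns$flatten_params(ref$params)
    groups <- unique(sub("\\..*$", "", names(after)))
    for (grp in groups) {
      nms <- names(after)[startsWith(names(after), grp)]
      moved <- any(vapply(nms, function(nm) {
        any(abs(after[[nm]]$value - before[[nm]]$value) > 0)
      }, logical(1)))
      expect_true(moved, label = paste(arch, grp, "parameters moved"))
    }
  }
})
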