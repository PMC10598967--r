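# The three base classifier architectures. Each maps a batch of L x 4
# one-hot windows to a probability per window via a sigmoid head, built on
# the autodiff tape in autograd.R.

#' Dilated 1-D convolution (reference primitive)
#'
#' Computes y_i = f(sum_{n=1..N} x_{i + k*n} * w_n + b) over all output
#' positions for which every tap index is valid (no padding), with i running
#' from 0, so the returned vector has length `length(x) - k*N + 1`. With
#' dilation `k = 1` this is a standard (valid) convolution/cross-correlation.
#'
#' This is the transparent scalar primitive; the network layers use a fused
#' "same"-padded batched equivalent, which reduces to this operation up to
#' boundary handling.
#'
#' @param x Numeric input vector.
#' @param weights Numeric filter weights (length N).
#' @param bias Scalar bias.
#' @param dilation Dilation rate k >= 1 (gaps of k-1 between taps).
#' @param activation Function applied elementwise to the result.
#' @return Numeric vector of length `length(x) - dilation*length(weights) + 1`.
#' @examples
#' dilated_conv1d(1:6, c(1, 1), dilation = 2)  # 6 8 10
#' @export
dilated_conv1d <- function(x, weights, bias = 0, dilation = 1L,
                           activation = identity) {
  N <- length(weights)
  k <- as.integer(dilation)
  stopifnot(k >= 1L, N >= 1L)
  Tn <- length(x)
  n_out <- Tn - k * N + 1L
  if (n_out < 1L) return(numeric(0))
  y <- numeric(n_out)
  taps <- k * seq_len(N)
  for (j in seq_len(n_out)) {
    y[j] <- sum(x[(j - 1L) + taps] * weights) + bias
  }
  activation(y)
}

#' Forward pass through a densely connected block (instrumentable)
#'
#' Layer i receives the channel-wise concatenation of the block input and all
#' previous layer outputs `[x0, x1, ..., x_{i-1}]`, so a block with X layers
#' realizes X(X+1)/2 layer-to-layer connections. `transform` is the
#' non-linear transformation H applied to the concatenation at each layer
#' (in the fitted models: a 1-D convolution followed by an ELU).
#'
#' @param x Input feature map: an L x C matrix (or an autodiff node).
#' @param n_layers Number of layers X >= 1.
#' @param transform Function mapping a feature-map node to a feature-map node.
#' @return List with `output` (concatenation of the input and every layer
#'   output), `n_connections` (the realized connection count) and
#'   `channel_history` (channel count of the concatenated state after each
#'   layer).
#' @export
dense_block_forward <- function(x, n_layers, transform) {
  node <- if (is.environment(x)) x else ag_const(as.matrix(x))
  feats <- list(node)
  n_conn <- 0L
  hist <- integer(n_layers)
  for (i in seq_len(n_layers)) {
    n_conn <- n_conn + length(feats)  # layer i consumes i feature maps
    inp <- if (length(feats) == 1L) feats[[1]] else ag_concat_cols(feats)
    out <- transform(inp)
    feats <- c(feats, list(out))
    hist[i] <- sum(vapply(feats, function(f) ncol(f$value), integer(1)))
  }
  output <- if (length(feats) == 1L) feats[[1]] else ag_concat_cols(feats)
  list(output = output, n_connections = n_conn, channel_history = hist)
}

#' Squeeze-and-excitation attention with residual reuse (reference form)
#'
#' Squeeze: per-channel global average over positions. Excitation: a
#' bottleneck affine pair (reduce then restore) with a sigmoid yielding
#' per-channel gates g in (0,1). The output re-uses the original feature
#' map residually: `x + g * x` (with `residual = FALSE` it is the classical
#' `g * x`).
#'
#' @param x L x C numeric matrix (single feature map).
#' @param params List with `W1` (C x Cr), `b1`, `W2` (Cr x C), `b2`; `NULL`
#'   initializes deterministically to zeros (gates 0.5).
#' @param gate_override Optional vector of C gate values forced in place of
#'   the learned excitation (testing hook).
#' @param residual Add the input back (default TRUE).
#' @return List with `output` (L x C matrix), `gates` (length-C vector) and
#'   `squeeze` (length-C channel means).
#' @export
se_block_apply <- function(x, params = NULL, gate_override = NULL,
                           residual = TRUE) {
  x <- as.matrix(x)
  C <- ncol(x)
  s <- colMeans(x)
  if (is.null(gate_override)) {
    if (is.null(params)) {
      cr <- max(1L, C %/% 4L)
      params <- list(W1 = matrix(0, C, cr), b1 = numeric(cr),
                     W2 = matrix(0, cr, C), b2 = numeric(C))
    }
    u <- drop(s %*% params$W1) + params$b1
    u[u < 0] <- exp(u[u < 0]) - 1  # ELU
    g <- 1 / (1 + exp(-(drop(u %*% params$W2) + params$b2)))
  } else {
    g <- rep_len(gate_override, C)
  }
  gated <- sweep(x, 2L, g, `*`)
  out <- if (residual) x + gated else gated
  list(output = out, gates = g, squeeze = s)
}

## ---- specs -----------------------------------------------------------------

#' Architecture specification for a base classifier
#'
#' Structural constants are fixed by the design (6 dense blocks with SE
#' attention; 3 dilated branches at rates 1/2/3; 6 multi-scale residual
#' blocks of 3 convolutional layers with 64 kernels and a 192-filter fusion
#' convolution); widths that the design leaves open are hyperparameters.
#'
#' @param architecture `"densenet_senet"`, `"dcnn_bilstm"` or `"msrn_bigru"`.
#' @param L Window length (41 for the delta = 20 design).
#' @param hyperparameters Named list overriding per-architecture defaults.
#' @return A `base_model_spec` object.
#' @export
base_model_spec <- function(architecture = c("densenet_senet", "dcnn_bilstm",
                                             "msrn_bigru"),
                            L = 41L, hyperparameters = list()) {
  architecture <- match.arg(architecture)
  defaults <- switch(architecture,
    densenet_senet = list(n_dense_blocks = 6L, layers_per_block = 2L,
                          growth = 8L, trunk_channels = 16L, kernel = 3L,
                          se_reduction = 4L, head_pool = 2L,
                          head_units = 32L),
    dcnn_bilstm = list(dilation_rates = c(1L, 2L, 3L), filters = 16L,
                       kernel = 3L, pool = 2L, lstm_units = 32L),
    msrn_bigru = list(n_msrb = 6L, block_channels = 64L, scales = c(3L, 5L),
                      fusion_filters = 192L, stem_pool = 2L, fusion_pool = 2L,
                      gru_units = 32L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(architecture = architecture, L = as.integer(L),
                 input_channels = 4L, hyperparameters = hp),
            class = "base_model_spec")
}

#' @export
print.base_model_spec <- function(x, ...) {
  cat(sprintf("<base_model_spec> %s (input %d x %d)\n", x$architecture, x$L,
              x$input_channels))
  invisible(x)
}

## ---- parameter initialization ---------------------------------------------

he_mat <- function(nr, nc, fan_in = nr) {
  ag_parameter(matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc))
}
zero_vec <- function(n, fill = 0) ag_parameter(rep(fill, n))

conv_par <- function(Cin, K, F_, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") ag_parameter(matrix(0, Cin * K, F_)) else
    he_mat(Cin * K, F_)
  list(W = W, b = zero_vec(F_))
}
ln_par <- function(C) list(g = zero_vec(C, fill = 1), b = zero_vec(C))
lin_par <- function(Cin, F_) list(W = he_mat(Cin, F_), b = zero_vec(F_))

lstm_par <- function(C, H) {
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = he_mat(C, 4 * H, fan_in = C), Wh = he_mat(H, 4 * H, fan_in = H),
       b = ag_parameter(b))
}
gru_par <- function(C, H) {
  list(Wx_zr = he_mat(C, 2 * H, fan_in = C),
       Wh_zr = he_mat(H, 2 * H, fan_in = H), b_zr = zero_vec(2 * H),
       Wx_n = he_mat(C, H, fan_in = C), Wh_n = he_mat(H, H, fan_in = H),
       b_n = zero_vec(H))
}
se_par <- function(C, reduction) {
  cr <- max(1L, C %/% reduction)
  list(W1 = he_mat(C, cr), b1 = zero_vec(cr),
       W2 = he_mat(cr, C), b2 = zero_vec(C))
}

## ---- tape-level building blocks -------------------------------------------

ag_se <- function(x, B, L, p, residual = TRUE) {
  s <- ag_pool_mean_positions(x, B, L)
  u <- ag_elu(ag_linear(s, p$W1, p$b1))
  g <- ag_sigmoid(ag_linear(u, p$W2, p$b2))
  gated <- ag_mul(x, ag_repeat_rows(g, L))
  if (residual) ag_add(x, gated) else gated
}

ag_lstm_direction <- function(x, B, L, p, H, reverse = FALSE,
                              return_sequence = FALSE) {
  h <- ag_const(matrix(0, B, H))
  cc <- ag_const(matrix(0, B, H))
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  base <- (seq_len(B) - 1L) * L
  hs <- if (return_sequence) vector("list", L)
  for (l in steps) {
    xt <- ag_gather_rows(x, base + l)
    z <- ag_linear2(xt, p$Wx, h, p$Wh, p$b)
    i_g <- ag_sigmoid(ag_slice_cols(z, 1:H))
    f_g <- ag_sigmoid(ag_slice_cols(z, (H + 1):(2 * H)))
    g_g <- ag_tanh(ag_slice_cols(z, (2 * H + 1):(3 * H)))
    o_g <- ag_sigmoid(ag_slice_cols(z, (3 * H + 1):(4 * H)))
    cc <- ag_add(ag_mul(f_g, cc), ag_mul(i_g, g_g))
    h <- ag_mul(o_g, ag_tanh(cc))
    if (return_sequence) hs[[l]] <- h
  }
  if (return_sequence) hs else h
}

ag_gru_direction <- function(x, B, L, p, H, reverse = FALSE,
                             return_sequence = FALSE) {
  h <- ag_const(matrix(0, B, H))
  steps <- if (reverse) rev(seq_len(L)) else seq_len(L)
  base <- (seq_len(B) - 1L) * L
  hs <- if (return_sequence) vector("list", L)
  for (l in steps) {
    xt <- ag_gather_rows(x, base + l)
    zr <- ag_sigmoid(ag_linear2(xt, p$Wx_zr, h, p$Wh_zr, p$b_zr))
    z <- ag_slice_cols(zr, 1:H)
    r <- ag_slice_cols(zr, (H + 1):(2 * H))
    n <- ag_tanh(ag_linear2(xt, p$Wx_n, ag_mul(r, h), p$Wh_n, p$b_n))
    # h <- (1 - z) * h + z * n  ==  h + z * (n - h)
    h <- ag_add(h, ag_mul(z, ag_add(n, ag_scale(h, -1))))
    if (return_sequence) hs[[l]] <- h
  }
  if (return_sequence) hs else h
}

## ---- architecture builders -------------------------------------------------

init_densenet_senet <- function(spec) {
  hp <- spec$hyperparameters
  tc <- hp$trunk_channels; gr <- hp$growth; K <- hp$kernel
  blocks <- lapply(seq_len(hp$n_dense_blocks), function(b) {
    Cin <- tc
    layers <- lapply(seq_len(hp$layers_per_block), function(i) {
      c(conv_par(Cin + (i - 1L) * gr, K, gr), ln = list(ln_par(gr)))
    })
    concat_c <- Cin + hp$layers_per_block * gr
    list(layers = layers,
         transition = conv_par(concat_c, 1L, tc),
         trans_ln = ln_par(tc),
         se = se_par(tc, hp$se_reduction))
  })
  Lp <- as.integer(ceiling(spec$L / hp$head_pool))
  list(se_in = se_par(spec$input_channels, hp$se_reduction),
       stem = conv_par(spec$input_channels, K, tc),
       stem_ln = ln_par(tc),
       blocks = blocks,
       head1 = lin_par(Lp * tc, hp$head_units),
       head2 = lin_par(hp$head_units, 1L))
}

forward_densenet_senet <- function(params, spec, x, B, training, dropout) {
  hp <- spec$hyperparameters
  L <- spec$L; K <- hp$kernel
  h <- ag_se(x, B, L, params$se_in)
  h <- ag_elu(ag_layernorm(ag_conv1d(h, params$stem$W, params$stem$b, B, L, K),
                           params$stem_ln$g, params$stem_ln$b))
  for (bl in params$blocks) {
    layer_i <- 0L
    db <- dense_block_forward(h, hp$layers_per_block, function(inp) {
      layer_i <<- layer_i + 1L
      p <- bl$layers[[layer_i]]
      ag_elu(ag_layernorm(ag_conv1d(inp, p$W, p$b, B, L, K), p$ln$g, p$ln$b))
    })
    h <- ag_elu(ag_layernorm(
      ag_conv1d(db$output, bl$transition$W, bl$transition$b, B, L, 1L),
      bl$trans_ln$g, bl$trans_ln$b))
    h <- ag_se(h, B, L, bl$se)
  }
  h <- ag_avgpool_positions(h, B, L, hp$head_pool)
  Lp <- as.integer(ceiling(L / hp$head_pool))
  pooled <- ag_flatten_positions(h, B, Lp)
  z <- ag_elu(ag_linear(pooled, params$head1$W, params$head1$b))
  z <- ag_dropout(z, dropout, training)
  ag_linear(z, params$head2$W, params$head2$b)
}

init_dcnn_bilstm <- function(spec) {
  hp <- spec$hyperparameters
  Fn <- hp$filters; K <- hp$kernel
  branches <- lapply(hp$dilation_rates, function(r) {
    list(conv1 = conv_par(spec$input_channels, K, Fn), ln1 = ln_par(Fn),
         conv2 = conv_par(Fn, K, Fn), ln2 = ln_par(Fn))
  })
  cat_c <- Fn * length(hp$dilation_rates)
  Lp <- as.integer(ceiling(spec$L / hp$pool))
  list(branches = branches,
       lstm_f = lstm_par(cat_c, hp$lstm_units),
       lstm_b = lstm_par(cat_c, hp$lstm_units),
       head = lin_par(2L * hp$lstm_units * Lp, 1L))
}

forward_dcnn_bilstm <- function(params, spec, x, B, training, dropout) {
  hp <- spec$hyperparameters
  L <- spec$L; K <- hp$kernel
  outs <- vector("list", length(hp$dilation_rates))
  for (j in seq_along(hp$dilation_rates)) {
    r <- hp$dilation_rates[j]
    p <- params$branches[[j]]
    h <- ag_layernorm(ag_conv1d(x, p$conv1$W, p$conv1$b, B, L, K,
                                dilation = r), p$ln1$g, p$ln1$b)
    h <- ag_relu(ag_layernorm(ag_conv1d(h, p$conv2$W, p$conv2$b, B, L, K,
                                        dilation = r), p$ln2$g, p$ln2$b))
    h <- ag_maxpool_positions(h, B, L, hp$pool)
    h <- ag_dropout(h, dropout, training)
    outs[[j]] <- h
  }
  Lp <- as.integer(ceiling(L / hp$pool))
  h <- ag_concat_cols(outs)
  hf <- ag_lstm_direction(h, B, Lp, params$lstm_f, hp$lstm_units,
                          return_sequence = TRUE)
  hb <- ag_lstm_direction(h, B, Lp, params$lstm_b, hp$lstm_units,
                          reverse = TRUE, return_sequence = TRUE)
  z <- ag_concat_cols(c(hf, hb))
  z <- ag_dropout(z, dropout, training)
  ag_linear(z, params$head$W, params$head$b)
}

init_msrn_bigru <- function(spec) {
  hp <- spec$hyperparameters
  Cb <- hp$block_channels
  blocks <- lapply(seq_len(hp$n_msrb), function(b) {
    list(conv_a = conv_par(Cb, hp$scales[1], Cb), ln_a = ln_par(Cb),
         conv_b = conv_par(Cb, hp$scales[2], Cb), ln_b = ln_par(Cb),
         fuse = conv_par(2L * Cb, 1L, Cb, init = "zero"))
  })
  list(stem = conv_par(spec$input_channels, 3L, Cb),
       stem_ln = ln_par(Cb),
       blocks = blocks,
       fusion = conv_par(Cb * hp$n_msrb, 1L, hp$fusion_filters),
       fusion_ln = ln_par(hp$fusion_filters),
       gru_f = gru_par(hp$fusion_filters, hp$gru_units),
       gru_b = gru_par(hp$fusion_filters, hp$gru_units),
       head = lin_par(2L * hp$gru_units *
                        as.integer(ceiling(ceiling(spec$L / hp$stem_pool) /
                                             hp$fusion_pool)), 1L))
}

forward_msrn_bigru <- function(params, spec, x, B, training, dropout) {
  hp <- spec$hyperparameters
  L <- spec$L
  h <- ag_elu(ag_layernorm(ag_conv1d(x, params$stem$W, params$stem$b, B, L, 3L),
                           params$stem_ln$g, params$stem_ln$b))
  h <- ag_maxpool_positions(h, B, L, hp$stem_pool)
  Lp <- as.integer(ceiling(L / hp$stem_pool))
  hier <- vector("list", hp$n_msrb)
  for (j in seq_len(hp$n_msrb)) {
    p <- params$blocks[[j]]
    a <- ag_relu(ag_layernorm(ag_conv1d(h, p$conv_a$W, p$conv_a$b, B, Lp,
                                        hp$scales[1]), p$ln_a$g, p$ln_a$b))
    b2 <- ag_relu(ag_layernorm(ag_conv1d(h, p$conv_b$W, p$conv_b$b, B, Lp,
                                         hp$scales[2]), p$ln_b$g, p$ln_b$b))
    m <- ag_concat_cols(list(a, b2))
    f <- ag_conv1d(m, p$fuse$W, p$fuse$b, B, Lp, 1L)
    h <- ag_add(h, f)  # residual pass-through (fuse conv starts at zero)
    hier[[j]] <- h
  }
  fused <- ag_relu(ag_layernorm(ag_conv1d(ag_concat_cols(hier),
                                          params$fusion$W, params$fusion$b,
                                          B, Lp, 1L),
                                params$fusion_ln$g, params$fusion_ln$b))
  fused <- ag_avgpool_positions(fused, B, Lp, hp$fusion_pool)
  Lq <- as.integer(ceiling(Lp / hp$fusion_pool))
  hf <- ag_gru_direction(fused, B, Lq, params$gru_f, hp$gru_units,
                         return_sequence = TRUE)
  hb <- ag_gru_direction(fused, B, Lq, params$gru_b, hp$gru_units,
                         reverse = TRUE, return_sequence = TRUE)
  z <- ag_concat_cols(c(hf, hb))
  z <- ag_dropout(z, dropout, training)
  ag_linear(z, params$head$W, params$head$b)
}

#' Build an untrained base model from a specification
#'
#' @param spec A [base_model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `base_model` object with `$params`, `$forward`, and
#'   `$structure_info` describing the realized graph (used by structural
#'   tests: block counts, dilation rates, kernel counts).
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "base_model_spec")) {
    stop("unknown architecture specification; use base_model_spec()")
  }
  hp <- spec$hyperparameters
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  params <- switch(spec$architecture,
                   densenet_senet = init_densenet_senet(spec),
                   dcnn_bilstm = init_dcnn_bilstm(spec),
                   msrn_bigru = init_msrn_bigru(spec),
                   stop("unknown architecture: ", spec$architecture))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  forward <- switch(spec$architecture,
                    densenet_senet = forward_densenet_senet,
                    dcnn_bilstm = forward_dcnn_bilstm,
                    msrn_bigru = forward_msrn_bigru)
  info <- switch(spec$architecture,
    densenet_senet = list(n_dense_blocks = hp$n_dense_blocks,
                          n_se_blocks_after_dense = hp$n_dense_blocks,
                          input_attention = TRUE,
                          connections_per_block =
                            hp$layers_per_block * (hp$layers_per_block + 1L) / 2),
    dcnn_bilstm = list(dilation_rates = hp$dilation_rates,
                       n_branches = length(hp$dilation_rates),
                       recurrent = "bilstm"),
    msrn_bigru = list(n_msrb = hp$n_msrb, convs_per_block = 3L,
                      kernels_per_layer = hp$block_channels,
                      fusion_filters = hp$fusion_filters,
                      scales = hp$scales, recurrent = "bigru"))
  structure(list(spec = spec, params = params, forward = forward,
                 structure_info = info, trained = FALSE,
                 training_meta = NULL),
            class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  cat(sprintf("<base_model> %s (%s)\n", x$spec$architecture,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Training configuration for base models
#'
#' The original method description fixes no training hyperparameters; these
#' defaults are package design choices, all overridable.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param early_stopping_patience Epochs without training-loss improvement
#'   before stopping.
#' @param dropout_rate Dropout rate used in the heads/branches.
#' @param seed Seed fixing initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, learning_rate = 1e-3,
                         optimizer = "adam", early_stopping_patience = 5L,
                         dropout_rate = 0.3, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            early_stopping_patience >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  if (!identical(optimizer, "adam")) stop("unsupported optimizer: ", optimizer)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "train_config")
}

# Build the (B*L) x 4 input slab for a subset of rows of a pre-encoded
# full-data matrix ((n*L) x 4).
batch_rows <- function(L, samples) {
  as.vector(vapply(samples, function(s) (s - 1L) * L + seq_len(L),
                   integer(L)))
}

#' Train a base model
#'
#' Minimizes mean binary cross-entropy with Adam; deterministic for a fixed
#' seed (single-threaded R; all randomness flows through the R RNG). Training
#' stops early when the epoch loss has not improved for
#' `early_stopping_patience` epochs.
#'
#' @param model An untrained (or trained) `base_model`.
#' @param windows Character vector of windows or a `site_dataset`.
#' @param y Binary labels (0/1), same length.
#' @param config A [train_config()].
#' @return The trained `base_model` with `$training_meta` (seed, epochs run,
#'   final train loss).
#' @export
train_base_model <- function(model, windows, y, config = train_config()) {
  stopifnot(inherits(model, "base_model"))
  if (inherits(windows, "site_dataset")) {
    if (missing(y) || is.null(y)) y <- dataset_labels(windows)
    windows <- windows$window
  }
  y <- as.numeric(y)
  n <- length(windows)
  if (n != length(y)) stop("length(windows) != length(y)")
  if (n < 2L || length(unique(y)) < 2L) {
    stop("training requires at least two samples with both classes present")
  }
  L <- model$spec$L
  if (any(nchar(windows) != L)) {
    stop("window length does not match model input length ", L)
  }
  Xfull <- onehot_batch_matrix(windows)
  # re-initialize weights under the training seed for full determinism
  model <- build_model(model$spec, seed = config$seed)
  set.seed(config$seed + 1L)
  params <- flatten_params(model$params)
  state <- adam_state(params)
  n_batches <- ceiling(n / config$batch_size)
  best <- Inf; wait <- 0L; epochs_run <- 0L; last_loss <- NA_real_
  for (ep in seq_len(config$epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      smp <- idx[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
      B <- length(smp)
      xb <- ag_const(Xfull[batch_rows(L, smp), , drop = FALSE])
      ag_tape_start()
      logits <- model$forward(model$params, model$spec, xb, B,
                              training = TRUE, dropout = config$dropout_rate)
      loss <- ag_bce_with_logits(logits, y[smp])
      if (!is.finite(loss$value)) {
        ag_tape_stop()
        stop("training diverged: non-finite loss at epoch ", ep,
             ", batch ", bi, " (try a lower learning rate)")
      }
      ag_zero_grad(params)
      ag_backward(loss)
      ag_tape_stop()
      state <- adam_step(params, state, lr = config$learning_rate)
      ep_loss <- ep_loss + loss$value * B
    }
    ep_loss <- ep_loss / n
    epochs_run <- ep
    last_loss <- ep_loss
    if (ep_loss < best - 1e-5) {
      best <- ep_loss
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stopping_patience) break
    }
  }
  model$trained <- TRUE
  model$training_meta <- list(seed = config$seed, epochs_run = epochs_run,
                              final_train_loss = last_loss)
  model
}

#' Predict site probabilities with a base model
#'
#' @param model A `base_model` (typically trained).
#' @param windows Character vector of windows or a `site_dataset`.
#' @param batch_size Prediction batch size.
#' @return Numeric vector of probabilities in \[0, 1\], in input order.
#' @export
predict_proba <- function(model, windows, batch_size = 256L) {
  stopifnot(inherits(model, "base_model"))
  if (inherits(windows, "site_dataset")) windows <- windows$window
  n <- length(windows)
  if (n == 0L) return(numeric(0))
  L <- model$spec$L
  if (any(nchar(windows) != L)) {
    stop("window length does not match model input length ", L)
  }
  Xfull <- onehot_batch_matrix(windows)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    smp <- i:min(i + batch_size - 1L, n)
    B <- length(smp)
    xb <- ag_const(Xfull[batch_rows(L, smp), , drop = FALSE])
    logits <- model$forward(model$params, model$spec, xb, B,
                            training = FALSE, dropout = 0)
    out[smp] <- 1 / (1 + exp(-as.vector(logits$value)))
    i <- i + batch_size
  }
  out
}
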