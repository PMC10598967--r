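# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Feature maps live as (B*L) x C matrices with position fastest within sample:
# row index (b-1)*L + l holds position l of sample b. All layers below keep
# that layout so convolutions reduce to gather + matmul (BLAS) and pooling to
# reshapes. Nodes are environments; parameters are nodes created off-tape that
# persist across batches and accumulate gradients.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_start <- function() .ag$tape <- new.env(parent = emptyenv())
ag_tape_stop <- function() .ag$tape <- NULL

ag_record <- function(node) {
  tp <- .ag$tape
  if (!is.null(tp)) {
    n <- if (is.null(tp$n)) 0L else tp$n
    tp[[as.character(n + 1L)]] <- node
    tp$n <- n + 1L
  }
  node
}

ag_node <- function(value, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(backward)) ag_record(nd)
  nd
}

# A constant / input node (no gradient tracked beyond accumulation).
ag_const <- function(value) ag_node(value)

# A learnable parameter: identical to a constant but flagged so optimizers
# can find it. Created while no tape is active.
ag_parameter <- function(value) {
  nd <- ag_node(value)
  nd$param <- TRUE
  nd
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Reverse sweep over the active tape. `loss` must be the last recorded node
# and evaluate to a scalar.
ag_backward <- function(loss) {
  tp <- .ag$tape
  if (is.null(tp)) stop("ag_backward() called without an active tape")
  loss$grad <- 1
  n <- tp$n
  for (i in seq.int(n, 1L)) {
    nd <- tp[[as.character(i)]]
    if (is.null(nd$grad)) next
    gs <- nd$backward(nd$grad, nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (is.null(nd$param)) nd$grad <- NULL  # free intermediate grads early
  }
  invisible(NULL)
}

## ---- elementary ops --------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$value %*% b$value, list(a, b), function(g, nd) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g, nd) list(g, g))
}

ag_mul <- function(a, b) {
  ag_node(a$value * b$value, list(a, b),
          function(g, nd) list(g * b$value, g * a$value))
}

# x: (n x C) node, bias: length-C parameter (stored as plain vector value).
ag_add_bias <- function(x, bias) {
  v <- x$value
  ag_node(v + rep(bias$value, each = nrow(v)), list(x, bias),
          function(g, nd) list(g, colSums(g)))
}

ag_scale <- function(x, k) {
  ag_node(x$value * k, list(x), function(g, nd) list(g * k))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g, nd) list(g * s * (1 - s)))
}

ag_tanh <- function(x) {
  t <- tanh(x$value)
  ag_node(t, list(x), function(g, nd) list(g * (1 - t * t)))
}

ag_relu <- function(x) {
  v <- x$value
  m <- v > 0
  ag_node(v * m, list(x), function(g, nd) list(g * m))
}

ag_elu <- function(x, alpha = 1) {
  v <- x$value
  neg <- v <= 0
  out <- v
  out[neg] <- alpha * (exp(v[neg]) - 1)
  ag_node(out, list(x), function(g, nd) {
    d <- matrix(1, nrow(v), ncol(v))
    d[neg] <- out[neg] + alpha
    list(g * d)
  })
}

# Gather rows by index; NA indices read as zero rows. Backward scatter-adds
# (duplicate indices are aggregated).
ag_gather_rows <- function(x, idx) {
  v <- x$value
  ok <- !is.na(idx)
  out <- matrix(0, length(idx), ncol(v))
  out[ok, ] <- v[idx[ok], , drop = FALSE]
  ag_node(out, list(x), function(g, nd) {
    dX <- matrix(0, nrow(v), ncol(v))
    ii <- idx[ok]
    agg <- rowsum(g[ok, , drop = FALSE], group = ii, reorder = TRUE)
    dX[as.integer(rownames(agg)), ] <- agg
    list(dX)
  })
}

ag_concat_cols <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(do.call(cbind, vals), nodes, function(g, nd) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ag_slice_cols <- function(x, cols) {
  nc <- ncol(x$value)
  ag_node(x$value[, cols, drop = FALSE], list(x), function(g, nd) {
    dX <- matrix(0, nrow(x$value), nc)
    dX[, cols] <- g
    list(dX)
  })
}

# Mean over positions within each sample: (B*L) x C -> B x C.
ag_pool_mean_positions <- function(x, B, L) {
  grp <- rep(seq_len(B), each = L)
  ag_node(rowsum(x$value, grp, reorder = TRUE) / L, list(x), function(g, nd) {
    list(g[grp, , drop = FALSE] / L)
  })
}

# Broadcast a B x C matrix over L positions -> (B*L) x C.
ag_repeat_rows <- function(x, L) {
  B <- nrow(x$value)
  grp <- rep(seq_len(B), each = L)
  ag_node(x$value[grp, , drop = FALSE], list(x), function(g, nd) {
    list(rowsum(g, grp, reorder = TRUE))
  })
}

# Max pooling along positions with window w ("same"-style ceiling division;
# ragged tail pools over the remaining positions).
ag_maxpool_positions <- function(x, B, L, w) {
  v <- x$value
  C <- ncol(v)
  Lp <- as.integer(ceiling(L / w))
  L2 <- Lp * w
  # (B*L) x C -> L x (B*C) with position fastest, pad to L2 with -Inf
  M <- matrix(as.vector(v), nrow = L)
  if (L2 > L) M <- rbind(M, matrix(-Inf, L2 - L, ncol(M)))
  M2 <- matrix(as.vector(M), nrow = w)  # w x (Lp*B*C)
  best <- M2[1L, ]
  amax <- rep.int(1L, ncol(M2))
  if (w > 1L) {
    for (i in 2:w) {
      upd <- M2[i, ] > best
      best[upd] <- M2[i, upd]
      amax[upd] <- i
    }
  }
  out <- matrix(best, nrow = B * Lp, ncol = C)
  ag_node(out, list(x), function(g, nd) {
    lin <- (seq_along(amax) - 1L) * w + amax  # index into padded L2 x (B*C) grid
    dPad <- numeric(L2 * B * C)
    dPad[lin] <- as.vector(g)
    dM <- matrix(dPad, nrow = L2)[seq_len(L), , drop = FALSE]
    list(matrix(as.vector(dM), nrow = B * L, ncol = C))
  })
}

# Average pooling along positions with window w (ragged tail averages the
# remaining positions only).
ag_avgpool_positions <- function(x, B, L, w) {
  v <- x$value
  C <- ncol(v)
  Lp <- as.integer(ceiling(L / w))
  L2 <- Lp * w
  counts <- rep.int(w, Lp)
  if (L2 > L) counts[Lp] <- w - (L2 - L)
  M <- matrix(as.vector(v), nrow = L)
  if (L2 > L) M <- rbind(M, matrix(0, L2 - L, ncol(M)))
  M2 <- matrix(as.vector(M), nrow = w)
  sums <- .colSums(M2, w, ncol(M2))
  cnt <- rep_len(counts, length(sums))
  out <- matrix(sums / cnt, nrow = B * Lp, ncol = C)
  ag_node(out, list(x), function(g, nd) {
    gv <- as.vector(g) / cnt
    dPad <- rep(gv, each = w)
    dM <- matrix(dPad, nrow = L2)[seq_len(L), , drop = FALSE]
    list(matrix(as.vector(dM), nrow = B * L, ncol = C))
  })
}

# Inverted dropout; identity when not training.
ag_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  v <- x$value
  mask <- matrix((stats::runif(length(v)) >= rate) / (1 - rate),
                 nrow(v), ncol(v))
  ag_node(v * mask, list(x), function(g, nd) list(g * mask))
}

## ---- fused layers ----------------------------------------------------------

# Index map for a dilated "same" convolution tap with offset `off`.
conv_tap_index <- function(B, L, off) {
  l <- rep.int(seq_len(L), B)
  src <- l + off
  idx <- rep((seq_len(B) - 1L) * L, each = L) + src
  idx[src < 1L | src > L] <- NA_integer_
  idx
}

conv_gather <- function(v, idx) {
  ok <- !is.na(idx)
  out <- matrix(0, length(idx), ncol(v))
  out[ok, ] <- v[idx[ok], , drop = FALSE]
  out
}

# 1-D convolution over positions, "same" padding, arbitrary dilation.
# W: (C*K) x F parameter (tap-major blocks of C rows), bias: length-F.
ag_conv1d <- function(x, W, bias, B, L, K, dilation = 1L) {
  C <- ncol(x$value)
  offs <- (seq_len(K) - (K + 1L) / 2) * dilation
  idxs <- lapply(offs, function(o) conv_tap_index(B, L, as.integer(o)))
  Xc <- do.call(cbind, lapply(idxs, function(i) conv_gather(x$value, i)))
  out <- Xc %*% W$value
  out <- out + rep(bias$value, each = nrow(out))
  ag_node(out, list(x, W, bias), function(g, nd) {
    dW <- crossprod(Xc, g)
    db <- colSums(g)
    dXc <- tcrossprod(g, W$value)
    dX <- matrix(0, nrow(x$value), C)
    for (t in seq_len(K)) {
      blk <- dXc[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
      ii <- idxs[[t]]
      ok <- !is.na(ii)
      # tap shifts are injective: plain indexed add is safe
      dX[ii[ok], ] <- dX[ii[ok], ] + blk[ok, , drop = FALSE]
    }
    list(dX, dW, db)
  })
}

# Fully connected layer: x %*% W + b.
ag_linear <- function(x, W, bias) {
  out <- x$value %*% W$value
  out <- out + rep(bias$value, each = nrow(out))
  ag_node(out, list(x, W, bias), function(g, nd) {
    list(tcrossprod(g, W$value), crossprod(x$value, g), colSums(g))
  })
}

# Fused two-input affine used by recurrent cells: a %*% Wa + b %*% Wb + bias.
ag_linear2 <- function(a, Wa, b, Wb, bias) {
  out <- a$value %*% Wa$value + b$value %*% Wb$value
  out <- out + rep(bias$value, each = nrow(out))
  ag_node(out, list(a, Wa, b, Wb, bias), function(g, nd) {
    list(tcrossprod(g, Wa$value), crossprod(a$value, g),
         tcrossprod(g, Wb$value), crossprod(b$value, g), colSums(g))
  })
}

# Reshape (B*L) x C feature map to B x (L*C), preserving position identity
# (column (c-1)*L + l holds channel c at position l).
ag_flatten_positions <- function(x, B, L) {
  v <- x$value
  C <- ncol(v)
  a <- array(as.vector(v), dim = c(L, B, C))
  out <- matrix(aperm(a, c(2, 1, 3)), nrow = B, ncol = L * C)
  ag_node(out, list(x), function(g, nd) {
    ga <- array(as.vector(g), dim = c(B, L, C))
    list(matrix(aperm(ga, c(2, 1, 3)), nrow = B * L, ncol = C))
  })
}

# Layer normalization across channels (per row = per position per sample),
# with learnable per-channel gain/shift. Batch-independent, so predictions
# do not depend on batch composition.
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  C <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  s <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / s
  out <- xhat * rep(gamma$value, each = nrow(v))
  out <- out + rep(beta$value, each = nrow(v))
  ag_node(out, list(x, gamma, beta), function(g, nd) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * rep(gamma$value, each = nrow(v))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / s
    list(dx, dgamma, dbeta)
  })
}

# Mean binary cross-entropy from logits (numerically stable softplus form).
ag_bce_with_logits <- function(logits, y) {
  z <- as.vector(logits$value)
  n <- length(z)
  sp <- pmax(z, 0) + log1p(exp(-abs(z)))  # softplus(z)
  loss <- mean(sp - y * z)
  ag_node(loss, list(logits), function(g, nd) {
    p <- 1 / (1 + exp(-z))
    list(matrix(g * (p - y) / n, ncol = 1L))
  })
}

## ---- optimizer -------------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) {
    list(m = array(0, dim = dim(p$value) %||% length(p$value)),
         v = array(0, dim = dim(p$value) %||% length(p$value)), t = 0L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[i]]
    st$t <- st$t + 1L
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * (g * g)
    mh <- st$m / (1 - beta1^st$t)
    vh <- st$v / (1 - beta2^st$t)
    p$value <- p$value - lr * mh / (sqrt(vh) + eps)
    state[[i]] <- st
  }
  state
}

# Flatten a nested list of parameter nodes into a flat named list.
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    el <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.environment(el)) {
      out[[key]] <- el
    } else if (is.list(el)) {
      out <- c(out, flatten_params(el, key))
    }
  }
  out
}
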