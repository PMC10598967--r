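# Two-layer stacking: out-of-fold base probabilities + flattened one-hot
# features feed a ridge-penalized logistic-regression meta-learner; the base
# models are then refit on the full training data for deployment.

#' Stub base-model specification (testing hook)
#'
#' A "model" that memorizes a window -> value lookup at construction and
#' returns it at prediction time, used to validate the stacking plumbing
#' independently of deep-model quality (e.g. a label oracle).
#'
#' @param windows Character vector of windows the stub knows about.
#' @param values Value returned for each window (e.g. the true labels).
#' @param name Identifier used in reports.
#' @return A `stub_model_spec`.
#' @export
stub_model_spec <- function(windows, values, name = "stub") {
  lookup <- as.numeric(values)
  names(lookup) <- as.character(windows)
  structure(list(architecture = name, lookup = lookup),
            class = "stub_model_spec")
}

spec_label <- function(spec) spec$architecture

# Internal dispatch so stubs and real architectures share the OOF plumbing.
fit_spec <- function(spec, windows, y, config) {
  if (inherits(spec, "stub_model_spec")) {
    structure(list(spec = spec), class = "stub_model")
  } else {
    train_base_model(build_model(spec, seed = config$seed), windows, y, config)
  }
}

predict_spec <- function(model, windows) {
  if (inherits(model, "stub_model")) {
    v <- model$spec$lookup[as.character(windows)]
    if (anyNA(v)) stop("stub model queried with unknown window(s)")
    unname(v)
  } else {
    predict_proba(model, windows)
  }
}

#' Stratified fold assignment
#'
#' @param y Binary labels (0/1).
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per sample; per-class fold sizes differ by
#'   at most one.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.numeric(y)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k) {
    stop("cannot stratify: a class has fewer samples (", min(table(y)),
         ") than folds (", k, ")")
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Out-of-fold base-model probabilities
#'
#' For each fold f and each architecture j, a model is trained on all folds
#' except f and predicts fold f, so entry (i, j) never saw sample i during
#' training. A per-fold log of training indices is returned for leakage
#' audits.
#'
#' @param specs List of `base_model_spec` (or stub) objects.
#' @param windows Character window vector or `site_dataset`.
#' @param y Binary labels (taken from the dataset if omitted).
#' @param k_folds Number of stacking-internal folds (default 5).
#' @param config A [train_config()]; per-fold seeds are derived from
#'   `seed`.
#' @param seed Seed for the fold assignment and derived training seeds.
#' @return An `oof_matrix`: list with `values` (n x length(specs) matrix),
#'   `fold` (fold id per sample) and `train_index_log` (per fold, the
#'   training indices used).
#' @export
oof_predictions <- function(specs, windows, y = NULL, k_folds = 5L,
                            config = train_config(), seed = 1L) {
  if (inherits(windows, "site_dataset")) {
    if (is.null(y)) y <- dataset_labels(windows)
    windows <- windows$window
  }
  y <- as.numeric(y)
  n <- length(windows)
  fold <- stratified_folds(y, k_folds, seed = seed)
  vals <- matrix(NA_real_, n, length(specs),
                 dimnames = list(NULL, vapply(specs, spec_label, character(1))))
  log_idx <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    log_idx[[f]] <- tr
    for (j in seq_along(specs)) {
      cfg <- config
      cfg$seed <- as.integer((seed + 131L * f + 17L * j) %% .Machine$integer.max)
      m <- fit_spec(specs[[j]], windows[tr], y[tr], cfg)
      vals[te, j] <- predict_spec(m, windows[te])
    }
  }
  structure(list(values = vals, fold = fold, train_index_log = log_idx),
            class = "oof_matrix")
}

#' Assemble meta-learner features
#'
#' Columns are the base probabilities (in spec order) followed by the
#' flattened original one-hot features; for L = 41 and three base models the
#' width is 3 + 41*4 = 167. No scaling is applied to the binary part.
#'
#' @param oof An `oof_matrix` (or a plain n x m probability matrix).
#' @param X_flat n x (L*4) matrix of flattened one-hot features (may have 0
#'   columns for the probabilities-only ablation).
#' @return n x (m + L*4) numeric matrix.
#' @export
assemble_meta_features <- function(oof, X_flat) {
  probs <- if (inherits(oof, "oof_matrix")) oof$values else as.matrix(oof)
  X_flat <- as.matrix(X_flat)
  if (nrow(probs) != nrow(X_flat)) {
    stop("row count mismatch: ", nrow(probs), " base-probability rows vs ",
         nrow(X_flat), " feature rows")
  }
  cbind(probs, X_flat)
}

#' Fit the logistic-regression meta-learner
#'
#' Maximizes the L2-penalized binomial log-likelihood by Newton iterations
#' (IRLS); the intercept is unpenalized. A weak default penalty stabilizes
#' the ~170-dimensional fit and keeps separable problems finite.
#'
#' @param meta_features n x p numeric matrix.
#' @param y Binary labels (0/1).
#' @param lambda L2 penalty on the non-intercept coefficients.
#' @param max_iter,tol Newton iteration controls.
#' @return A `meta_model` with `weights`, `intercept`, `converged`,
#'   `iterations` and `final_gradient_norm`.
#' @export
fit_meta <- function(meta_features, y, lambda = 1e-3, max_iter = 100L,
                     tol = 1e-8) {
  X <- cbind(1, as.matrix(meta_features))
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  gnorm <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    gnorm <- max(abs(grad))
    if (gnorm < tol) break
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  converged <- gnorm < max(tol, 1e-4)
  if (!converged) {
    warning("meta-learner IRLS stopped after ", it,
            " iterations with gradient norm ", signif(gnorm, 3))
  }
  structure(list(intercept = beta[1], weights = beta[-1], lambda = lambda,
                 converged = converged, iterations = it,
                 final_gradient_norm = gnorm),
            class = "meta_model")
}

#' Predict probabilities with a fitted meta-learner
#' @param meta A `meta_model`.
#' @param meta_features Feature matrix with the training-time width.
#' @return Probabilities in \[0, 1\].
#' @export
predict_meta <- function(meta, meta_features) {
  Z <- as.matrix(meta_features)
  if (ncol(Z) != length(meta$weights)) {
    stop("meta-feature width ", ncol(Z), " does not match fitted width ",
         length(meta$weights))
  }
  drop(1 / (1 + exp(-(meta$intercept + Z %*% meta$weights))))
}

#' Fit the full stacking ensemble
#'
#' Generates out-of-fold probabilities for every base architecture, fits the
#' meta-learner on \[base probabilities, flattened one-hot\] features, then
#' refits each base model on all training data for deployment.
#'
#' @inheritParams oof_predictions
#' @param use_original_features Concatenate the flattened one-hot features
#'   (default TRUE; FALSE gives the probabilities-only ablation).
#' @param lambda Meta-learner L2 penalty.
#' @return A `stacked_ensemble`.
#' @export
fit_stacked_ensemble <- function(specs, windows, y = NULL, k_folds = 5L,
                                 config = train_config(), seed = 1L,
                                 use_original_features = TRUE,
                                 lambda = 1e-3) {
  if (inherits(windows, "site_dataset")) {
    if (is.null(y)) y <- dataset_labels(windows)
    windows <- windows$window
  }
  y <- as.numeric(y)
  L <- nchar(windows[1])
  oof <- oof_predictions(specs, windows, y, k_folds = k_folds,
                         config = config, seed = seed)
  X_flat <- if (use_original_features) {
    encode_windows(windows, "onehot", flatten = TRUE)
  } else {
    matrix(numeric(0), nrow = length(windows), ncol = 0)
  }
  Z <- assemble_meta_features(oof, X_flat)
  meta <- fit_meta(Z, y, lambda = lambda)
  base_models <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    cfg <- config
    cfg$seed <- as.integer((seed + 977L * j) %% .Machine$integer.max)
    base_models[[j]] <- fit_spec(specs[[j]], windows, y, cfg)
  }
  names(base_models) <- vapply(specs, spec_label, character(1))
  structure(list(base_models = base_models, meta_model = meta,
                 feature_recipe = list(L = L, n_base = length(specs),
                                       base_order = names(base_models),
                                       use_original_features =
                                         use_original_features,
                                       meta_width = ncol(Z)),
                 oof = oof, k_folds = k_folds, seed = seed),
            class = "stacked_ensemble")
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf("<stacked_ensemble> %d base models (%s), meta width %d\n",
              x$feature_recipe$n_base,
              paste(x$feature_recipe$base_order, collapse = ", "),
              x$feature_recipe$meta_width))
  invisible(x)
}

#' Predict site probabilities with a stacked ensemble
#'
#' @param ensemble A `stacked_ensemble`.
#' @param windows Character window vector or `site_dataset` (lengths must
#'   match the training recipe).
#' @return Probabilities in \[0, 1\], in input order.
#' @export
predict_ensemble <- function(ensemble, windows) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  if (inherits(windows, "site_dataset")) windows <- windows$window
  if (length(windows) == 0L) return(numeric(0))
  L <- ensemble$feature_recipe$L
  if (any(nchar(windows) != L)) {
    stop("window length does not match ensemble recipe length ", L)
  }
  probs <- vapply(ensemble$base_models, function(m) predict_spec(m, windows),
                  numeric(length(windows)))
  probs <- matrix(probs, nrow = length(windows))
  X_flat <- if (ensemble$feature_recipe$use_original_features) {
    encode_windows(windows, "onehot", flatten = TRUE)
  } else {
    matrix(numeric(0), nrow = length(windows), ncol = 0)
  }
  predict_meta(ensemble$meta_model, assemble_meta_features(probs, X_flat))
}

## ---- serialization ---------------------------------------------------------

params_to_list <- function(x) {
  lapply(x, function(el) {
    if (is.environment(el)) {
      if (is.matrix(el$value)) {
        list(.mat = TRUE, dim = dim(el$value), data = as.vector(el$value))
      } else {
        list(.mat = FALSE, data = as.vector(el$value))
      }
    } else if (is.list(el)) params_to_list(el) else el
  })
}

params_from_list <- function(x) {
  lapply(x, function(el) {
    if (is.list(el) && !is.null(el$.mat)) {
      v <- as.numeric(el$data)
      ag_parameter(if (isTRUE(el$.mat)) matrix(v, el$dim[1], el$dim[2]) else v)
    } else if (is.list(el)) params_from_list(el) else el
  })
}

#' Save a stacked ensemble as a directory of JSON files
#'
#' Layout: `ensemble.json` (recipe, meta-learner, fold bookkeeping) plus one
#' `base_<j>_<architecture>.json` weight file per base model. Everything is
#' plain text.
#'
#' @param ensemble A `stacked_ensemble` of real (non-stub) base models.
#' @param dir Output directory (created if needed).
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    package = "m6AmStack",
    feature_recipe = ensemble$feature_recipe,
    k_folds = ensemble$k_folds, seed = ensemble$seed,
    meta_model = list(intercept = ensemble$meta_model$intercept,
                      weights = ensemble$meta_model$weights,
                      lambda = ensemble$meta_model$lambda),
    base = lapply(seq_along(ensemble$base_models), function(j) {
      m <- ensemble$base_models[[j]]
      if (inherits(m, "stub_model")) stop("cannot serialize stub base models")
      list(file = sprintf("base_%d_%s.json", j, m$spec$architecture),
           architecture = m$spec$architecture, L = m$spec$L,
           hyperparameters = m$spec$hyperparameters,
           training_meta = m$training_meta)
    }))
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (j in seq_along(ensemble$base_models)) {
    m <- ensemble$base_models[[j]]
    jsonlite::write_json(params_to_list(m$params),
                         file.path(dir, meta$base[[j]]$file),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a stacked ensemble saved by [save_ensemble()]
#' @param dir Ensemble directory.
#' @return A `stacked_ensemble`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  base_models <- lapply(meta$base, function(b) {
    spec <- base_model_spec(b$architecture, L = b$L,
                            hyperparameters = lapply(b$hyperparameters, unlist))
    m <- build_model(spec, seed = 1L)
    raw <- jsonlite::read_json(file.path(dir, b$file), simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
    m$params <- params_from_list(raw)
    m$trained <- TRUE
    m$training_meta <- b$training_meta
    m
  })
  names(base_models) <- vapply(meta$base, function(b) b$architecture,
                               character(1))
  fr <- meta$feature_recipe
  fr$L <- as.integer(fr$L)
  fr$n_base <- as.integer(fr$n_base)
  fr$base_order <- unlist(fr$base_order)
  meta_model <- structure(list(intercept = meta$meta_model$intercept,
                               weights = unlist(meta$meta_model$weights),
                               lambda = meta$meta_model$lambda,
                               converged = TRUE, iterations = NA_integer_,
                               final_gradient_norm = NA_real_),
                          class = "meta_model")
  structure(list(base_models = base_models, meta_model = meta_model,
                 feature_recipe = fr, oof = NULL,
                 k_folds = meta$k_folds, seed = meta$seed),
            class = "stacked_ensemble")
}
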