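brute_confusion <- function(y, s, thr) {
  TP <- FP <- TN <- FN <- 0L
  for (i in seq_along(y)) {
    pred <- s[i] >= thr
    if (pred && y[i] == 1) TP <- TP + 1L
    if (pred && y[i] == 0) FP <- FP + 1L
    if (!pred && y[i] == 0) TN <- TN + 1L
    if (!pred && y[i] == 1) FN <- FN + 1L
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN)
}

brute_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

brute_aupr <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    pred <- s >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    prec <- tp / (tp + fp)
    rec <- tp / sum(y == 1)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("confusion counts follow the tie-goes-to-positive rule", {
  y <- c(1, 1, 0, 0)
  cc <- confusion_counts(y, c(0.9, 0.8, 0.1, 0.2), 0.5)
  expect_identical(c(cc$TP, cc$FP, cc$TN, cc$FN), c(2L, 0L, 2L, 0L))
  # all scores exactly at threshold: everything predicted positive
  cc2 <- confusion_counts(y, rep(0.5, 4), 0.5)
  expect_identical(cc2$TP + cc2$FP, 4L)
  expect_error(confusion_counts(numeric(0), numeric(0)), "empty")

  set.seed(24)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    y <- rbinom(n, 1, 0.5)
    s <- round(runif(n), 2)
    got <- confusion_counts(y, s, 0.5)
    want <- brute_confusion(y, s, 0.5)
    expect_identical(got$TP, want$TP)
    expect_identical(got$FP, want$FP)
    expect_identical(got$TN, want$TN)
    expect_identical(got$FN, want$FN)
  }
})

test_that("threshold metrics reproduce hand-computed values", {
  perfect <- classification_metrics(list(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(perfect[c("Sn", "Sp", "ACC", "MCC")],
               list(Sn = 1, Sp = 1, ACC = 1, MCC = 1))
  m <- classification_metrics(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(m$Sn, 0.75)
  expect_equal(m$Sp, 0.5)
  expect_equal(m$ACC, 0.625)
  expect_equal(round(m$MCC, 4), 0.2582)
  # zero-denominator convention: flagged 0, never an error
  z <- classification_metrics(list(TP = 0, FN = 0, TN = 4, FP = 1))
  expect_identical(z$Sn, 0)
  expect_true(all(c("Sn", "MCC") %in% z$degenerate))
})

test_that("AUROC equals exhaustive pair enumeration", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(25)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse grid to exercise ties
    expect_equal(auroc(y, s), brute_auroc(y, s))
  }
})

test_that("AUPR equals an explicit threshold sweep", {
  expect_equal(aupr(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  set.seed(26)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)
    expect_equal(aupr(y, s), brute_aupr(y, s))
  }
  # label-independent scores: AUPR concentrates near the prevalence
  set.seed(27)
  y <- rbinom(4000, 1, 0.2)
  s <- runif(4000)
  expect_lt(abs(aupr(y, s) - 0.2), 0.05)
})

test_that("balanced-data accuracy identity and null MCC hold", {
  set.seed(28)
  y <- rep(c(1, 0), 250)
  s <- runif(500)
  r <- metric_report(y, s)
  expect_equal(r$ACC, (r$Sn + r$Sp) / 2)
  expect_identical(r$n_pos, 500L %/% 2L)
  # predictions independent of labels: MCC near 0 in expectation
  mccs <- replicate(40, {
    classification_metrics(confusion_counts(sample(y), s, 0.5))$MCC
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("cross_validate honours stratification, stubs and determinism", {
  ds <- generate_dataset(33, 27, delta = 5, seed = 29)
  y <- dataset_labels(ds)
  # an always-correct deterministic pipeline
  oracle_factory <- function(tr_w, tr_y) {
    lookup <- stats::setNames(y, ds$window)
    function(w) unname(lookup[w])
  }
  cv <- cross_validate(oracle_factory, ds, k = 5, repeats = 2, seed = 7)
  expect_identical(nrow(cv$folds), 10L)
  expect_true(cv$leakage_audit)
  expect_equal(unname(cv$mean[["ACC"]]), 1)
  expect_equal(unname(cv$sd[["ACC"]]), 0)
  # fold sizes differ by at most one per class (stratification contract)
  fold <- stratified_folds(y, 5, seed = 7)
  for (cls in c(0, 1)) {
    expect_lte(diff(range(table(fold[y == cls]))), 1)
  }
  cv2 <- cross_validate(oracle_factory, ds, k = 5, repeats = 2, seed = 7)
  expect_identical(cv$folds, cv2$folds)
})

test_that("negative resampling is reproducible, sized, and stable", {
  pos <- strong_dataset(100, 0, seed = 30)$window
  pool <- strong_dataset(0, 800, seed = 31)$window
  sizes <- integer(0)
  logistic_factory <- function(tr_w, tr_y) {
    sizes <<- c(sizes, length(tr_w))
    m <- fit_meta(encode_windows(tr_w, "onehot", flatten = TRUE), tr_y,
                  lambda = 1)
    function(w) predict_meta(m, encode_windows(w, "onehot", flatten = TRUE))
  }
  res <- negative_resampling_experiment(pos, pool, logistic_factory,
                                        n_repeats = 3, ratio = 1, k = 5,
                                        seed = 11)
  expect_length(res, 3L)
  accs <- vapply(res, function(s) unname(s$mean[["ACC"]]), numeric(1))
  expect_lt(diff(range(accs)), 0.05)
  res2 <- negative_resampling_experiment(pos, pool, logistic_factory,
                                         n_repeats = 3, ratio = 1, k = 5,
                                         seed = 11)
  expect_identical(lapply(res, function(s) s$folds),
                   lapply(res2, function(s) s$folds))

  # ratio 4 draws the 1:4 imbalanced design
  sizes <- integer(0)
  res4 <- negative_resampling_experiment(pos[1:50], pool, logistic_factory,
                                         n_repeats = 1, ratio = 4, k = 5,
                                         seed = 12)
  expect_true(all(sizes == 200))  # 4/5 of 50 + 200 samples per training fold
  expect_error(negative_resampling_experiment(pos, pool[1:50],
                                              logistic_factory, ratio = 1),
               "pool")
})
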