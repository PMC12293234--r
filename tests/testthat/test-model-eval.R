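# Model assembly, fold partitioning, metric formulas, the training loop and
# the hybrid classical classifiers.

make_tiny_epochs <- function(n_per_class = 10, seed = 20) {
  # linearly separable at tiny scale: class 1 carries a strong 4 Hz tone
  # (fs 16, 32-sample epochs), class 0 is noise
  set.seed(seed)
  n <- 2 * n_per_class
  eps <- array(rnorm(n * 2 * 32, sd = 0.5), c(n, 2, 32))
  t <- (0:31) / 16
  for (i in seq_len(n_per_class)) {
    eps[n_per_class + i, 1, ] <- eps[n_per_class + i, 1, ] +
      3 * sin(2 * pi * 4 * t + runif(1, 0, 2 * pi))
    eps[n_per_class + i, 2, ] <- eps[n_per_class + i, 2, ] +
      3 * cos(2 * pi * 4 * t + runif(1, 0, 2 * pi))
  }
  epoch_set(eps, rep(0:1, each = n_per_class),
            rep(sprintf("s%02d", 1:n), each = 1), 16)
}

test_that("a built model produces two logits per epoch and prints", {
  m <- build_model(tiny_model_config(), seed = 1)
  fw <- model_forward(m, array(rnorm(2 * 2 * 32), c(2, 2, 32)))
  expect_equal(dim(fw$logits), c(2, 2))
  expect_output(print(m), "eegfuse_model")
})

test_that("ablation variants change the parameter structure as declared", {
  full <- build_model(tiny_model_config(), seed = 1)
  expect_false(is.null(full$params$acda))
  no_acda <- build_model(tiny_model_config(ablation = "no_acda"), seed = 1)
  expect_null(no_acda$params$acda)
  # concatenation head: fused width = time width + model width
  expect_equal(ncol(no_acda$params$head$W), 6 + 4)
  only_time <- build_model(tiny_model_config(ablation = "only_time"),
                           seed = 1)
  expect_null(only_time$params$freq)          # the STFT path does not exist
  expect_null(only_time$params$acda)
  only_freq <- build_model(tiny_model_config(ablation = "only_freq"),
                           seed = 1)
  expect_null(only_freq$params$time)
  no_dc <- build_model(tiny_model_config(ablation = "no_dynamic_conv"),
                       seed = 1)
  expect_equal(ncol(no_dc$params$time$blocks[[1]]$dyconv1$Wk), 1)  # static
  no_cbam <- build_model(tiny_model_config(ablation = "no_cbam"), seed = 1)
  expect_null(no_cbam$params$freq$cbam)
  expect_error(model_config(2, 32, ablation = "bogus"), "unknown")
})

test_that("fold partitions are disjoint, exhaustive and size-balanced", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(10:200, 1); k <- sample(2:min(8, n), 1)
    sp <- make_folds(n, k, seed = i)
    tests <- lapply(sp, `[[`, "test_ids")
    expect_equal(sort(unlist(tests)), seq_len(n))
    sizes <- lengths(tests)
    expect_lte(max(sizes) - min(sizes), 1)
    for (f in sp) {
      expect_length(intersect(f$train_ids, f$test_ids), 0)
      expect_setequal(c(f$train_ids, f$test_ids), seq_len(n))
    }
  }
  expect_identical(make_folds(50, 5, seed = 3), make_folds(50, 5, seed = 3))
  expect_error(make_folds(4, 5), "more folds")
})

test_that("subject-level folds never split a subject", {
  ep <- make_tiny_epochs(10)
  ep$subject_ids <- rep(sprintf("subj%d", 1:5), each = 4)
  sp <- make_folds(ep, 5, seed = 2, subject_level = TRUE)
  seen <- lapply(sp, function(f) unique(ep$subject_ids[f$test_ids]))
  expect_equal(sort(unlist(seen)), sort(unique(ep$subject_ids)))
  expect_equal(anyDuplicated(unlist(seen)), 0L)
})

test_that("metric formulas match the worked case and a brute-force oracle", {
  # worked case: TP=50 TN=40 FP=10 FN=0
  y_true <- c(rep(1, 50), rep(0, 50))
  y_pred <- c(rep(1, 50), rep(1, 10), rep(0, 40))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$TP, 50); expect_equal(m$TN, 40)
  expect_equal(m$FP, 10); expect_equal(m$FN, 0)
  expect_equal(round(m$accuracy, 2), 90.00)
  expect_equal(round(m$precision, 2), 83.33)
  expect_equal(round(m$recall, 2), 100.00)
  expect_equal(round(m$specificity, 2), 80.00)
  expect_equal(round(m$f1, 2), 90.91)
  # brute-force confusion oracle on random label vectors
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    mm <- suppressWarnings(compute_metrics(yt, yp))
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1
      if (yt[j] == 0 && yp[j] == 0) tn <- tn + 1
      if (yt[j] == 0 && yp[j] == 1) fp <- fp + 1
      if (yt[j] == 1 && yp[j] == 0) fn <- fn + 1
    }
    expect_equal(mm$TP + mm$TN + mm$FP + mm$FN, n)
    expect_equal(mm$accuracy, 100 * (tp + tn) / n)
    if (tp + fp > 0) expect_equal(mm$precision, 100 * tp / (tp + fp))
    if (tp + fn > 0) expect_equal(mm$recall, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(mm$specificity, 100 * tn / (tn + fp))
    if (2 * tp + fp + fn > 0)
      expect_equal(mm$f1, 100 * 2 * tp / (2 * tp + fp + fn))
  }
  # perfect and all-wrong predictions
  p <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_true(all(unlist(p[c("accuracy", "precision", "recall",
                              "specificity", "f1")]) == 100))
  w <- suppressWarnings(compute_metrics(c(0, 1), c(1, 0)))
  expect_equal(w$accuracy, 0); expect_equal(w$specificity, 0)
  warns <- capture_warnings(compute_metrics(c(0, 0), c(0, 0)))
  expect_true(any(grepl("undefined", warns)))
})

test_that("training reduces the loss on separable data and logs tau", {
  ep <- make_tiny_epochs(16)
  first_last <- vapply(1:3, function(s) {
    tc <- train_config(batch_size = 8, epochs = 5, lr = 0.01, folds = 4,
                       seed = s, K = 2, tau0 = 25)
    sp <- make_folds(ep, 4, seed = s)[[1]]
    r <- train_fold(ep, sp, tc, tiny_model_config())
    expect_equal(r$history$tau[1], 25)
    c(first = r$history$loss[1], last = r$history$loss[5])
  }, numeric(2))
  expect_lt(median(first_last["last", ]), median(first_last["first", ]))
})

test_that("tau reaches 1 from training epoch 10 and runs are seed-deterministic", {
  ep <- make_tiny_epochs(6)
  tc <- train_config(batch_size = 8, epochs = 11, lr = 0.01, folds = 3,
                     seed = 4, K = 2, tau0 = 25)
  sp <- make_folds(ep, 3, seed = 4)[[1]]
  r1 <- train_fold(ep, sp, tc, tiny_model_config())
  expect_equal(r1$history$tau[10], 1)
  expect_equal(r1$history$tau[11], 1)
  r2 <- train_fold(ep, sp, tc, tiny_model_config())
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$metrics$accuracy, r2$metrics$accuracy)
})

test_that("cross_validate aggregates fold metrics exactly", {
  ep <- make_tiny_epochs(8)
  tc <- train_config(batch_size = 8, epochs = 2, lr = 0.01, folds = 3,
                     seed = 5, K = 2, tau0 = 5)
  agg <- cross_validate(ep, tc, tiny_model_config())
  folds <- attr(agg, "folds")
  expect_length(folds, 3)
  accs <- vapply(folds, function(f) f$metrics$accuracy, 0)
  expect_equal(agg$accuracy, mean(accs), tolerance = 1e-10)
  expect_equal(agg$accuracy_variance, var(accs), tolerance = 1e-10)
})

test_that("extracted features have the fused width; only_time equals pooled Xt", {
  ep <- make_tiny_epochs(4)
  m <- build_model(tiny_model_config(), seed = 2)
  f <- extract_features(m, ep)
  expect_equal(dim(f), c(8, 4))                  # fused width = model width
  expect_equal(extract_features(m, ep), f)
  mt <- build_model(tiny_model_config(ablation = "only_time"), seed = 2)
  ft <- extract_features(mt, ep)
  expect_equal(ncol(ft), 6)                      # last block width
  xt <- time_branch_forward(matrix(ep$epochs[1, , ], 2), mt$params$time,
                            tokens = 4, tau = mt$tau)
  expect_equal(ft[1, ], colMeans(xt), tolerance = 1e-10)
})

test_that("hybrid classifiers are exact on separable features, chance on shuffled", {
  set.seed(23)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  feats <- cbind(rnorm(n) + 6 * labels, rnorm(n) - 6 * labels)
  splits <- make_folds(n, 3, seed = 1)
  for (clf in c("rf", "knn", "svm")) {
    agg <- hybrid_classify(feats, labels, splits, clf, seed = 1)
    expect_equal(agg$accuracy, 100)
    agg2 <- hybrid_classify(feats, labels, splits, clf, seed = 1)
    expect_identical(agg$accuracy, agg2$accuracy)
  }
  shuffled <- sample(labels)
  accs <- vapply(c("rf", "knn", "svm"), function(clf)
    hybrid_classify(cbind(rnorm(n), rnorm(n)), shuffled, splits, clf,
                    seed = 2)$accuracy, 0)
  expect_true(all(abs(accs - 50) <= 25))
  expect_error(hybrid_classify(feats, labels, splits, "mlp"), "arg")
})

test_that("a 1x1 grid search returns its only candidate pair", {
  ep <- make_tiny_epochs(6)
  tc <- train_config(batch_size = 8, epochs = 1, lr = 0.01, folds = 3,
                     seed = 6, K = 2, tau0 = 5)
  g <- grid_search(ep, K_grid = 3, tau0_grid = 10, tc, tiny_model_config())
  expect_equal(g$K, 3)
  expect_equal(g$tau0, 10)
  expect_equal(nrow(g$table), 1)
  expect_false(is.na(g$table$loss))
})
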