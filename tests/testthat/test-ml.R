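# stratified split, metrics, classifier benchmark, feature importance

test_that("stratified_split preserves class proportions and is seeded", {
  y <- rep(c("a", "b"), c(60, 40))
  sp <- stratified_split(y, 0.7, seed = 1)
  expect_equal(sum(y[sp$train] == "a"), 42)
  expect_equal(sum(y[sp$train] == "b"), 28)
  expect_equal(sum(y[sp$test] == "a"), 18)
  expect_equal(sum(y[sp$test] == "b"), 12)
  expect_identical(sp, stratified_split(y, 0.7, seed = 1))
  expect_false(identical(sp, stratified_split(y, 0.7, seed = 2)))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_error(stratified_split(c("a", "a", "b"), 0.7), "2 members")
})

test_that("per-class train share never deviates by more than one record", {
  set.seed(21)
  for (r in 1:50) {
    k <- sample(2:5, 1)
    y <- sample(letters[1:k], 30 + sample(100, 1), replace = TRUE,
                prob = runif(k) + 0.3)
    if (any(table(y) < 2)) next
    sp <- stratified_split(y, 0.7, seed = r)
    got <- table(factor(y[sp$train], levels = sort(unique(y))))
    want <- 0.7 * table(y)
    expect_true(all(abs(got - want) <= 1))
  }
})

test_that("metrics_from_confusion matches hand evaluation and brute force", {
  # perfect prediction
  perf <- diag(c(5, 7, 9))
  m <- metrics_from_confusion(perf)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  cm <- rbind(c(50, 10), c(5, 35))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$per_class$precision[1], 50 / 55, tolerance = 1e-12)
  expect_equal(m$per_class$recall[1], 50 / 60, tolerance = 1e-12)
  expect_equal(m$per_class$f1[1],
               2 * (50 / 55) * (50 / 60) / (50 / 55 + 50 / 60),
               tolerance = 1e-12)

  # brute-force one-vs-rest on random matrices
  set.seed(22)
  for (r in 1:100) {
    K <- sample(2:5, 1)
    cm <- matrix(rpois(K * K, 8), K, K)
    if (sum(cm) == 0 || any(rowSums(cm) == 0)) next
    m <- suppressWarnings(metrics_from_confusion(cm))
    prec <- rec <- f1 <- numeric(K)
    for (k in 1:K) {
      tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
      prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1[k] <- if (prec[k] + rec[k] == 0) 0 else
        2 * prec[k] * rec[k] / (prec[k] + rec[k])
    }
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
    expect_equal(m$precision, mean(prec), tolerance = 1e-12)
    expect_equal(m$recall, mean(rec), tolerance = 1e-12)
    expect_equal(m$f1, mean(f1), tolerance = 1e-12)
    # micro identity: weighted recall equals accuracy
    w <- suppressWarnings(metrics_from_confusion(cm, "weighted"))
    expect_equal(w$recall, m$accuracy, tolerance = 1e-12)
  }
})

test_that("the literal printed accuracy form stays available for audit", {
  cm <- rbind(c(50, 10), c(5, 35))
  lit <- metrics_from_confusion(cm, paper_literal = TRUE)
  # macro average of (TP+TN)/(TP+TN+FN): class1 (50+35)/(95+10),
  # class2 (35+50)/(85+5)
  expect_equal(lit$accuracy, mean(c(85 / 95, 85 / 90)), tolerance = 1e-12)
})

test_that("auc_ovr matches the Mann-Whitney construction", {
  set.seed(23)
  y <- rep(c("p", "q"), each = 50)
  s <- cbind(p = rnorm(100, ifelse(y == "p", 1, 0)), q = 0)
  s[, "q"] <- -s[, "p"]
  r <- rank(s[, "p"])
  auc_p <- (sum(r[y == "p"]) - 50 * 51 / 2) / 2500
  expect_equal(auc_ovr(s, y), auc_p, tolerance = 1e-12)  # both classes equal
  expect_equal(auc_ovr(cbind(p = as.numeric(y == "p"),
                             q = as.numeric(y == "q")), y), 1)
})

test_that("all available families separate 3-class blobs", {
  set.seed(24)
  n <- 300
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  X <- matrix(rnorm(n * 4, sd = 0.5), n, 4)
  X[, 1] <- X[, 1] + c(0, 3, 6)[as.integer(y)]
  X[, 2] <- X[, 2] + c(3, 0, -3)[as.integer(y)]
  sp <- stratified_split(y, 0.7, seed = 1)
  b <- run_benchmark(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                     seed = 1)
  ok <- b$results[b$results$status == "ok", ]
  expect_gte(nrow(ok), 5)  # xgboost may legitimately be absent
  expect_true(all(ok$accuracy >= 0.95))
  expect_true(all(ok$auc_roc >= 0.95))
  expect_true(all(unlist(ok[, c("precision", "recall", "f1")]) >= 0 &
                    unlist(ok[, c("precision", "recall", "f1")]) <= 1))
  # skipped families appear explicitly, never silently dropped
  expect_setequal(b$results$model,
                  c("RandomForest", "GradientBoosting", "SVM", "KNN",
                    "Logistic Regression", "XGBoost"))
})

test_that("shuffled labels drive accuracy to chance", {
  set.seed(25)
  n <- 3000; K <- 4
  y <- factor(sample(letters[1:K], n, replace = TRUE))
  X <- matrix(rnorm(n * 6), n, 6)
  sp <- stratified_split(y, 0.7, seed = 2)
  b <- run_benchmark(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                     models = c("logistic_regression", "knn",
                                "gradient_boosting"),
                     seed = 2)
  expect_true(all(abs(b$results$accuracy - 1 / K) < 0.05))
})

test_that("benchmark runs are deterministic given the seed", {
  set.seed(26)
  y <- factor(rep(c("a", "b", "c"), each = 60))
  X <- matrix(rnorm(180 * 5), 180, 5)
  X[, 1] <- X[, 1] + as.integer(y)
  sp <- stratified_split(y, 0.7, seed = 3)
  args <- list(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
               models = c("random_forest", "gradient_boosting"), seed = 9)
  b1 <- do.call(run_benchmark, args)
  b2 <- do.call(run_benchmark, args)
  expect_identical(b1$results, b2$results)
})

test_that("gradient-boosting importance finds a planted signal", {
  set.seed(27)
  n <- 2000; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(ifelse(X[, 3] + rnorm(n, sd = 0.3) > 0, "pos", "neg"))
  fit <- cmmnet:::.fit_gbm(X, y, seed = 1)
  imp <- feature_importance(fit, paste0("f", 1:p))
  expect_equal(imp$feature[1], "f3")
  expect_gt(imp$importance[1], 0.5)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
})

test_that("all-noise features never dominate importance", {
  set.seed(28)
  p <- 10
  mx <- replicate(10, {
    X <- matrix(rnorm(400 * p), 400, p)
    y <- factor(sample(c("u", "v"), 400, TRUE))
    imp <- feature_importance(cmmnet:::.fit_gbm(X, y, seed = 1),
                              paste0("f", 1:p))
    imp$importance[1]
  })
  expect_true(all(mx < 3 / p))
})
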