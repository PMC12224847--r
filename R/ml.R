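# Classifier benchmark: stratified split, native model families, confusion
# matrices, the four point metrics, one-vs-rest AUC, and gradient-boosting
# feature importance.
#
# None of the usual classifier packages are assumed at runtime; the
# families are implemented natively (softmax regression, k-nearest
# neighbors, random forest and gradient boosting over the compiled CART,
# and a linear squared-hinge SVM). XGBoost is used only when the xgboost
# namespace happens to be installed; otherwise the family is reported as
# skipped.

#' Stratified train/test split
#'
#' Splits row indices so that each class keeps the train fraction within
#' rounding (at least one record per class on each side). Deterministic
#' given `seed`.
#'
#' @param labels class labels.
#' @param train_fraction fraction assigned to the training set.
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 0L) {
  y <- factor(labels)
  if (any(table(y) < 2))
    stop("every class needs at least 2 members to stratify", call. = FALSE)
  .with_seed(seed, {
    train <- integer(0)
    for (l in levels(y)) {
      idx <- which(y == l)
      ntr <- round(train_fraction * length(idx))
      ntr <- min(max(ntr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx)[seq_len(ntr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(y), train))
  })
}

#' Confusion matrix (rows = true, columns = predicted)
#'
#' @param true,pred label vectors; levels are unified.
#' @return K x K integer matrix.
#' @export
confusion_matrix <- function(true, pred) {
  lv <- union(levels(factor(true)), levels(factor(pred)))
  table(factor(true, levels = lv), factor(pred, levels = lv))
}

#' Point metrics from a confusion matrix
#'
#' Accuracy is trace/total. Precision, recall and F1 are computed per class
#' one-vs-rest (TP/(TP+FP), TP/(TP+FN), harmonic mean) and aggregated by
#' macro or weighted average; classes never predicted get precision 0 with
#' a warning. `paper_literal = TRUE` switches accuracy to the per-class
#' macro average of (TP+TN)/(TP+TN+FN), the literal printed formula, kept
#' only for auditability.
#'
#' @param cm square count matrix, rows = true, columns = predicted.
#' @param average `"macro"` (default) or `"weighted"` (by true class size).
#' @param paper_literal use the literal printed accuracy denominator.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, and the
#'   `per_class` data.frame.
#' @export
metrics_from_confusion <- function(cm, average = c("macro", "weighted"),
                                   paper_literal = FALSE) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  if (is.null(rownames(cm)))
    rownames(cm) <- colnames(cm) <- as.character(seq_len(K))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  if (any(tp + fp == 0))
    warning("class(es) absent from predictions get precision 0",
            call. = FALSE)
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  wts <- if (average == "macro") rep(1 / K, K) else rowSums(cm) / total
  acc <- if (paper_literal) sum(wts * (tp + tn) / (tp + tn + fn))
         else sum(tp) / total
  list(accuracy = acc,
       precision = sum(wts * prec),
       recall = sum(wts * rec),
       f1 = sum(wts * f1),
       per_class = data.frame(class = rownames(cm), tp = tp, fp = fp,
                              fn = fn, tn = tn, precision = prec,
                              recall = rec, f1 = f1))
}

#' One-vs-rest multiclass AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class's score column against all
#' other classes, averaged (macro) over the classes present.
#'
#' @param scores n x K matrix of class scores (columns named by class).
#' @param labels true labels.
#' @return scalar macro AUC.
#' @export
auc_ovr <- function(scores, labels) {
  labels <- as.character(labels)
  aucs <- vapply(colnames(scores), function(cl) {
    pos <- labels == cl
    npos <- sum(pos); nneg <- sum(!pos)
    if (npos == 0 || nneg == 0) return(NA_real_)
    r <- rank(scores[, cl])
    (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

## ---- native model families ------------------------------------------------

.fit_logistic <- function(X, y, seed) {
  fit_multinomial(X, y, lambda = 1e-4)
}
.predict_logistic <- function(fit, X) predict(fit, X)

.fit_knn <- function(X, y, seed, k = 5L) {
  list(X = X, y = factor(y), k = k)
}
.predict_knn <- function(fit, X) {
  lv <- levels(fit$y)
  tr <- fit$X
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * tcrossprod(X, tr)
  P <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(X))) {
    nb <- order(d2[i, ])[seq_len(fit$k)]
    tt <- table(fit$y[nb])
    P[i, ] <- as.numeric(tt) / fit$k
  }
  P
}

.fit_rf <- function(X, y, seed, ntree = 100L, max_depth = 12L,
                    min_node = 5L) {
  y <- factor(y)
  K <- nlevels(y)
  yc <- as.numeric(y) - 1
  mtry <- max(1L, floor(sqrt(ncol(X))))
  .with_seed(seed, {
    trees <- lapply(seq_len(ntree), function(b) {
      idx <- sample.int(nrow(X), nrow(X), replace = TRUE) - 1L
      .grow_tree_cpp(X, yc, K, TRUE, idx, mtry, max_depth, min_node,
                     sample.int(.Machine$integer.max, 1))
    })
    list(trees = trees, levels = levels(y))
  })
}
.predict_rf <- function(fit, X) {
  P <- Reduce(`+`, lapply(fit$trees, function(tr) .predict_tree_cpp(tr, X)))
  P <- P / length(fit$trees)
  colnames(P) <- fit$levels
  P
}

.fit_gbm <- function(X, y, seed, n_rounds = 100L, shrinkage = 0.1,
                     max_depth = 3L, min_node = 10L) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  Fm <- matrix(0, n, K)
  allidx <- seq_len(n) - 1L
  imp <- numeric(ncol(X))
  .with_seed(seed, {
    rounds <- vector("list", n_rounds)
    for (r in seq_len(n_rounds)) {
      E <- exp(Fm - apply(Fm, 1, max))
      P <- E / rowSums(E)
      trees <- vector("list", K)
      for (k in seq_len(K)) {
        g <- Y[, k] - P[, k]
        tr <- .grow_tree_cpp(X, g, 1L, FALSE, allidx, ncol(X), max_depth,
                             min_node, sample.int(.Machine$integer.max, 1))
        imp <- imp + tr$importance
        pred <- .predict_tree_cpp(tr, X)[, 1]
        Fm[, k] <- Fm[, k] + shrinkage * pred
        trees[[k]] <- tr
      }
      rounds[[r]] <- trees
    }
    list(rounds = rounds, levels = levels(y), shrinkage = shrinkage,
         importance = imp)
  })
}
.predict_gbm <- function(fit, X) {
  K <- length(fit$levels)
  Fm <- matrix(0, nrow(X), K)
  for (trees in fit$rounds)
    for (k in seq_len(K))
      Fm[, k] <- Fm[, k] + fit$shrinkage * .predict_tree_cpp(trees[[k]], X)[, 1]
  E <- exp(Fm - apply(Fm, 1, max))
  P <- E / rowSums(E)
  colnames(P) <- fit$levels
  P
}

# linear one-vs-rest SVM, L2-regularized squared hinge, optimized by BFGS
.fit_svm <- function(X, y, seed, C = 1) {
  y <- factor(y)
  W <- sapply(levels(y), function(cl) {
    t <- ifelse(y == cl, 1, -1)
    obj <- function(w) {
      f <- X %*% w[-1] + w[1]
      xi <- pmax(0, 1 - t * f)
      0.5 * sum(w[-1]^2) + C * sum(xi^2)
    }
    grd <- function(w) {
      f <- as.numeric(X %*% w[-1] + w[1])
      xi <- pmax(0, 1 - t * f)
      g <- -2 * C * t * xi
      c(sum(g), crossprod(X, g) + w[-1])
    }
    stats::optim(numeric(ncol(X) + 1), obj, grd, method = "BFGS",
                 control = list(maxit = 200))$par
  })
  list(W = W, levels = levels(y))
}
.predict_svm <- function(fit, X) {
  D <- cbind(1, X) %*% fit$W
  E <- exp(D - apply(D, 1, max))
  P <- E / rowSums(E)
  colnames(P) <- fit$levels
  P
}

.fit_xgboost <- function(X, y, seed) {
  if (!requireNamespace("xgboost", quietly = TRUE)) return(NULL)
  y <- factor(y)
  booster <- xgboost::xgboost(
    data = X, label = as.numeric(y) - 1, nrounds = 100,
    params = list(objective = "multi:softprob", num_class = nlevels(y),
                  max_depth = 3, eta = 0.1, seed = seed),
    verbose = 0)
  list(booster = booster, levels = levels(y))
}
.predict_xgboost <- function(fit, X) {
  P <- matrix(stats::predict(fit$booster, X), nrow(X),
              length(fit$levels), byrow = TRUE)
  colnames(P) <- fit$levels
  P
}

.model_registry <- function() {
  list(
    random_forest = list(label = "RandomForest", fit = .fit_rf,
                         predict = .predict_rf),
    gradient_boosting = list(label = "GradientBoosting", fit = .fit_gbm,
                             predict = .predict_gbm),
    svm = list(label = "SVM", fit = .fit_svm, predict = .predict_svm),
    knn = list(label = "KNN", fit = .fit_knn, predict = .predict_knn),
    logistic_regression = list(label = "Logistic Regression",
                               fit = .fit_logistic,
                               predict = .predict_logistic),
    xgboost = list(label = "XGBoost", fit = .fit_xgboost,
                   predict = .predict_xgboost)
  )
}

#' Benchmark the classifier families on a train/test split
#'
#' Trains each family with its documented default hyperparameters on the
#' training rows and evaluates on the test rows: accuracy, macro precision,
#' recall, F1 (weighted versions are also emitted), one-vs-rest macro AUC,
#' and the confusion matrix. A family whose backing is unavailable at
#' runtime (XGBoost without the optional package) is reported as skipped
#' rather than dropped silently.
#'
#' @param X_train,X_test numeric matrices (preprocessed with training-set
#'   scaling only).
#' @param y_train,y_test class labels.
#' @param models subset of `names(.model_registry())`; default all six.
#' @param seed seed forwarded to every stochastic learner.
#' @return a `cmm_benchmark`: list with `results` data.frame (one row per
#'   family), `confusions`, `fits`.
#' @export
run_benchmark <- function(X_train, y_train, X_test, y_test,
                          models = names(.model_registry()), seed = 0L) {
  reg <- .model_registry()
  unknown <- setdiff(models, names(reg))
  if (length(unknown))
    stop("unknown model families: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  y_train <- factor(y_train)
  y_test <- factor(y_test, levels = levels(y_train))
  rows <- list(); confs <- list(); fits <- list()
  for (m in models) {
    spec <- reg[[m]]
    fit <- spec$fit(X_train, y_train, seed = seed)
    if (is.null(fit)) {
      rows[[m]] <- data.frame(model = spec$label, status = "skipped",
                              accuracy = NA_real_, precision = NA_real_,
                              recall = NA_real_, f1 = NA_real_,
                              auc_roc = NA_real_,
                              precision_weighted = NA_real_,
                              recall_weighted = NA_real_,
                              f1_weighted = NA_real_)
      next
    }
    P <- spec$predict(fit, X_test)
    pred <- factor(colnames(P)[max.col(P, ties.method = "first")],
                   levels = levels(y_train))
    cm <- confusion_matrix(y_test, pred)
    mac <- suppressWarnings(metrics_from_confusion(cm, "macro"))
    wtd <- suppressWarnings(metrics_from_confusion(cm, "weighted"))
    rows[[m]] <- data.frame(model = spec$label, status = "ok",
                            accuracy = mac$accuracy,
                            precision = mac$precision, recall = mac$recall,
                            f1 = mac$f1,
                            auc_roc = auc_ovr(P, y_test),
                            precision_weighted = wtd$precision,
                            recall_weighted = wtd$recall,
                            f1_weighted = wtd$f1)
    confs[[m]] <- cm
    fits[[m]] <- fit
  }
  structure(list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 confusions = confs, fits = fits, seed = seed),
            class = "cmm_benchmark")
}

#' Gradient-boosting feature importance
#'
#' Total squared-error (impurity) reduction attributed to each feature over
#' all boosting rounds, normalized to sum to 1 and sorted descending.
#'
#' @param fit a gradient-boosting fit from [run_benchmark()]
#'   (`fits$gradient_boosting`) or `.fit_gbm`.
#' @param feature_names column names of the design matrix.
#' @return data.frame with `feature` and `importance`, descending.
#' @export
feature_importance <- function(fit, feature_names) {
  imp <- fit$importance
  if (is.null(imp)) stop("fit carries no importance scores", call. = FALSE)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = feature_names, importance = imp)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
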