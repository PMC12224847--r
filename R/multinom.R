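# Maximum-likelihood multinomial (softmax) logistic regression by
# Newton-Raphson with the full (K-1)p x (K-1)p observed information. Shared
# by the odds-ratio module (which needs Wald standard errors) and the
# logistic-regression classifier (which uses a small ridge for stability on
# separable data).

#' Fit a multinomial logistic model
#'
#' Log-odds of each non-reference class against the reference are linear in
#' the design. Newton-Raphson with step halving; Wald standard errors come
#' from the inverse observed information at the optimum.
#'
#' @param X numeric design matrix (no intercept column; one is added).
#' @param y factor of class labels.
#' @param reference reference level (default: first level).
#' @param lambda ridge penalty on non-intercept coefficients (0 for pure
#'   maximum likelihood).
#' @param maxit,tol Newton iteration controls.
#' @return a `cmm_multinom`: `coef` ((p+1) x (K-1)), `se`, `vcov`,
#'   `converged`, `separation` (heuristic flag: non-convergence, runaway
#'   coefficients, or exploded standard errors), `levels`, `reference`.
#' @export
fit_multinomial <- function(X, y, reference = NULL, lambda = 0,
                            maxit = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(reference)) reference <- levels(y)[1]
  if (!reference %in% levels(y)) stop("unknown reference level", call. = FALSE)
  y <- stats::relevel(y, ref = reference)
  lev <- levels(y)
  K <- length(lev)
  if (K < 2) stop("need at least 2 classes", call. = FALSE)
  n <- nrow(X)
  Xd <- cbind("(Intercept)" = 1, X)
  p <- ncol(Xd)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  pen <- rep(lambda, p); pen[1] <- 0  # no penalty on the intercept
  beta <- matrix(0, p, K - 1)

  nll <- function(B) {
    eta <- cbind(0, Xd %*% B)
    eta <- eta - apply(eta, 1, max)
    ll <- sum(eta[Y == 1]) - sum(log(rowSums(exp(eta))))
    -ll + 0.5 * sum(pen * B^2)
  }
  probs <- function(B) {
    eta <- cbind(0, Xd %*% B)
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    e / rowSums(e)
  }

  converged <- FALSE
  f_old <- nll(beta)
  for (it in seq_len(maxit)) {
    P <- probs(beta)
    grad <- matrix(0, p, K - 1)
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in 2:K) {
      grad[, k - 1] <- crossprod(Xd, P[, k] - Y[, k]) + pen * beta[, k - 1]
      for (l in 2:K) {
        wkl <- P[, k] * ((k == l) - P[, l])
        blk <- crossprod(Xd, Xd * wkl)
        if (k == l) blk <- blk + diag(pen, p)
        H[((k - 2) * p + 1):((k - 1) * p),
          ((l - 2) * p + 1):((l - 1) * p)] <- blk
      }
    }
    step <- tryCatch(solve(H, as.vector(grad)), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- beta - alpha * matrix(step, p, K - 1)
      f_new <- nll(cand)
      if (is.finite(f_new) && f_new <= f_old + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    f_old <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }

  P <- probs(beta)
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (k in 2:K) for (l in 2:K) {
    wkl <- P[, k] * ((k == l) - P[, l])
    blk <- crossprod(Xd, Xd * wkl)
    if (k == l) blk <- blk + diag(pen, p)
    H[((k - 2) * p + 1):((k - 1) * p), ((l - 2) * p + 1):((l - 1) * p)] <- blk
  }
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, nrow(H), ncol(H)))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1)
  dimnames(beta) <- dimnames(se) <- list(colnames(Xd), lev[-1])
  separation <- !converged || any(abs(beta) > 20) || anyNA(se) ||
    any(se > 1e3)
  structure(list(coef = beta, se = se, vcov = V, converged = converged,
                 separation = separation, levels = lev,
                 reference = reference, lambda = lambda,
                 feature_names = colnames(X)),
            class = "cmm_multinom")
}

#' Predicted class probabilities from a multinomial fit
#'
#' @param object a `cmm_multinom`.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return n x K probability matrix (columns in `object$levels` order).
#' @export
predict.cmm_multinom <- function(object, newdata, ...) {
  Xd <- cbind(1, as.matrix(newdata))
  eta <- cbind(0, Xd %*% object$coef)
  eta <- eta - apply(eta, 1, max)
  e <- exp(eta)
  P <- e / rowSums(e)
  colnames(P) <- object$levels
  P
}
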