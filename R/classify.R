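# Logistic classification, stratified folds, ROC/AUC machinery.

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an intercept.  Convergence when the
#' largest coefficient update falls below `tol` (default 1e-8) or after
#' `max_iter` iterations.  On detected quasi-separation (diverging
#' coefficients or non-convergence with near-degenerate fitted
#' probabilities) the model is refitted with a small ridge penalty (1e-4, on
#' the slopes only) and flagged.  Zero-variance predictor columns receive a
#' zero slope.
#'
#' @param predictors `N x d` matrix (`d >= 1`).
#' @param y Binary response with both classes present.
#' @param ridge Ridge penalty on the slopes (default 0; the separation
#'   fallback uses 1e-4).
#' @param max_iter,tol IRLS iteration controls.
#' @return A `logistic_model`: list with `coefficients` (intercept first),
#'   `converged`, `n_iter`, `separation`, `ridge`.
#' @export
fit_logistic <- function(predictors, y, ridge = 0, max_iter = 100L,
                         tol = 1e-8) {
  X <- as.matrix(predictors)
  y <- as.numeric(y)
  N <- nrow(X)
  if (length(y) != N) stop("dimension mismatch", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("response contains a single class", call. = FALSE)
  keep <- apply(X, 2, function(col) diff(range(col)) > 0)
  fit <- .irls_logistic(X[, keep, drop = FALSE], y, ridge, max_iter, tol)
  separation <- !fit$converged || max(abs(fit$beta_std)) > 1e2
  used_ridge <- ridge
  if (separation && ridge == 0) {
    used_ridge <- 1e-4
    fit <- .irls_logistic(X[, keep, drop = FALSE], y, used_ridge,
                          max_iter, tol)
  }
  coefs <- numeric(ncol(X) + 1L)
  coefs[1L] <- fit$beta[1L]
  coefs[1L + which(keep)] <- fit$beta[-1L]
  names(coefs) <- c("(Intercept)",
                    colnames(X) %||% paste0("x", seq_len(ncol(X))))
  structure(list(coefficients = coefs, converged = fit$converged,
                 n_iter = fit$n_iter, separation = separation,
                 ridge = used_ridge, n_predictors = ncol(X)),
            class = "logistic_model")
}

# IRLS on internally standardized predictors (centering/scaling keeps the
# normal equations well-conditioned for predictors like the aBMD analogue,
# whose variance is tiny relative to its mean); coefficients are mapped back
# to the original scale.  The ridge penalty acts on the standardized slopes.
.irls_logistic <- function(X, y, ridge, max_iter, tol) {
  mu <- if (ncol(X)) colMeans(X) else numeric(0)
  sds <- if (ncol(X)) apply(X, 2, sd) else numeric(0)
  sds[!is.finite(sds) | sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  A <- cbind(1, Xs)
  d <- ncol(A)
  beta <- numeric(d)
  beta[1] <- qlogis(mean(y))
  pen <- diag(c(0, rep(ridge, d - 1L)), d)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- as.vector(A %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    M <- crossprod(A, A * w) + pen
    new_beta <- tryCatch(solve(M, crossprod(A, w * z)),
                         error = function(e)
                           solve(M + diag(1e-10, d), crossprod(A, w * z)))
    new_beta <- as.vector(new_beta)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (!all(is.finite(beta))) { converged <- FALSE; break }
    if (delta < tol) { converged <- TRUE; break }
  }
  slopes <- if (d > 1L) beta[-1L] / sds else numeric(0)
  intercept <- beta[1L] - sum(slopes * mu)
  list(beta = c(intercept, slopes), beta_std = beta,
       converged = converged, n_iter = it)
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model (%d predictors)%s%s\n", x$n_predictors,
              if (x$separation) " [quasi-separation: ridge fallback]" else "",
              if (!x$converged) " [NOT converged]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted fracture probabilities
#' @param object A `logistic_model`.
#' @param newdata `n x d` predictor matrix.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.logistic_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_predictors)
    stop("newdata has wrong number of predictors", call. = FALSE)
  plogis(as.vector(cbind(1, X) %*% object$coefficients))
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately with the given seed and deals subjects
#' round-robin into `k` folds, starting each class where the previous class
#' left off so that fold sizes (and per-fold class counts) differ by at most
#' one from perfect stratification.  Deterministic given the seed.
#'
#' @param y Binary status array.
#' @param k Number of folds, at most the smaller class count.
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `fold_of` (length-`N` integers in
#'   `1..k`), `k`, `seed`.
#' @export
#' @examples
#' f <- stratified_kfold(rep(c(0, 1), c(47, 46)), k = 10, seed = 1)
#' table(f$fold_of)
stratified_kfold <- function(y, k, seed) {
  y <- as.numeric(y)
  k <- as.integer(k)
  counts <- table(y)
  if (length(counts) < 2L) stop("y must contain both classes", call. = FALSE)
  if (k < 2L || k > min(counts))
    stop("k must be between 2 and the smaller class count", call. = FALSE)
  fold_of <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(fold_of = fold_of, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' ROC curve and AUC
#'
#' AUC by the Mann-Whitney pair statistic: the fraction of
#' (fractured, non-fractured) pairs where the fractured subject scores
#' higher, ties counted 1/2 (equivalently, computed from mid-ranks).  ROC
#' points are produced by a descending-score threshold sweep, starting at
#' (0,0) and ending at (1,1) with both coordinates non-decreasing.
#'
#' @param scores Numeric risk scores.
#' @param y Binary status (1 = fracture).
#' @return List with `roc_points` (two-column matrix FPR, TPR) and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
roc_auc <- function(scores, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- which(diff(ss) != 0)
  grp_end <- c(grp_end, length(ss))
  tp <- cumsum(ys)[grp_end] / n1
  fp <- cumsum(1 - ys)[grp_end] / n0
  roc <- rbind(c(0, 0), cbind(FPR = fp, TPR = tp))
  if (roc[nrow(roc), 1] != 1 || roc[nrow(roc), 2] != 1)
    roc <- rbind(roc, c(1, 1))
  colnames(roc) <- c("FPR", "TPR")
  list(roc_points = roc, auc = auc)
}

#' Bootstrap confidence interval for the AUC
#'
#' Class-stratified bootstrap percentile interval at 95%: subjects are
#' resampled with replacement within each class (so every resample keeps
#' both classes), the AUC recomputed, and the 2.5/97.5 percentiles
#' reported.  Seeded and deterministic.
#'
#' @param scores,y As in [roc_auc()].
#' @param n_boot Number of resamples (>= 100; default 2000).
#' @param seed Integer seed.
#' @return Length-2 vector `c(lo, hi)`.
#' @export
auc_ci <- function(scores, y, n_boot = 2000L, seed = 1L) {
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  y <- as.numeric(y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) stop("both classes required", call. = FALSE)
  aucs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(i1[sample.int(length(i1), replace = TRUE)],
               i0[sample.int(length(i0), replace = TRUE)])
      roc_auc(scores[idx], y[idx])$auc
    }, numeric(1))
  })
  unname(quantile(aucs, c(0.025, 0.975)))
}

#' Confusion matrix at a probability threshold
#'
#' Scores at or above the threshold predict fracture.
#'
#' @param scores Predicted probabilities.
#' @param y Binary status.
#' @param threshold Decision threshold (default 0.5).
#' @return 2 x 2 integer matrix, rows = actual (fracture, non-fracture),
#'   columns = predicted.
#' @export
confusion_at <- function(scores, y, threshold = 0.5) {
  y <- as.numeric(y)
  pred <- as.numeric(scores >= threshold)
  m <- matrix(c(sum(y == 1 & pred == 1), sum(y == 1 & pred == 0),
                sum(y == 0 & pred == 1), sum(y == 0 & pred == 0)),
              2, 2, byrow = TRUE,
              dimnames = list(actual = c("fracture", "non-fracture"),
                              predicted = c("fracture", "non-fracture")))
  m
}
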