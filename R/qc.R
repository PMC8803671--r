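# Leave-one-out Cook's-distance screening on the PLS component regression.
#
# Raw shape/intensity matrices have p >> N, so the classical OLS influence
# formulation is not applicable to them directly; the influence screen acts
# on the regression of the status array on the leading PLS components
# (scores as regressors).  The PLS decomposition is fitted once on the full
# cohort; Cook's distance of each subject is then computed by the
# definitionally literal leave-one-out route: refit the component regression
# without the subject and measure the shift of all fitted values.

#' Leave-one-out Cook's distance outlier screen
#'
#' Fits the `m`-component PLS decomposition on the full cohort, then, for
#' each subject `i`, refits the regression of the status array on the
#' components without subject `i`, predicts all `N` subjects, and computes
#' `D_i = sum_k (yhat_k - yhat_k^(-i))^2 / (p_eff * s^2)` with
#' `p_eff = m + 1` (components plus intercept) and `s^2` the residual mean
#' square of the full-cohort regression.  This is the classical Cook's
#' distance of the component regression, computed by explicit refits rather
#' than the hat-matrix shortcut.
#'
#' @param X `N x p` data matrix (shape or intensity).
#' @param y Binary status array.
#' @param m Number of PLS components in the screened regression (default 2).
#' @param threshold Flagging threshold for `D_i`; default 1 (the classical
#'   rule for an influential observation).  The `4/N` convention can be
#'   supplied instead but flags a handful of benign subjects on any clean
#'   cohort.
#' @return An `outlier_report`: list with `cooks_d` (length `N`),
#'   `threshold` and `flagged` (indices with `D_i > threshold`).
#' @export
cooks_distance_loo <- function(X, y, m = 2L, threshold = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  N <- nrow(X)
  if (N < 3L) stop("need at least 3 subjects", call. = FALSE)
  threshold <- threshold %||% 1
  m <- as.integer(m)

  full <- fit_pls(X, y, m = m)
  m_used <- full$n_modes
  Z <- cbind(1, full$scores[, seq_len(m_used), drop = FALSE])
  cf <- lm.fit(Z, y)
  yhat <- as.vector(Z %*% cf$coefficients)
  p_eff <- m_used + 1L
  s2 <- sum((y - yhat)^2) / max(N - p_eff, 1L)
  D <- numeric(N)
  if (s2 <= 1e-12 * mean((y - mean(y))^2)) {
    warning("full model fits the status array perfectly; all Cook's ",
            "distances reported as 0")
  } else {
    for (i in seq_len(N)) {
      ci <- lm.fit(Z[-i, , drop = FALSE], y[-i])$coefficients
      yhat_i <- as.vector(Z %*% ci)
      D[i] <- sum((yhat - yhat_i)^2) / (p_eff * s2)
    }
  }
  structure(list(cooks_d = D, threshold = threshold,
                 flagged = which(D > threshold)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Cook's distance LOO screen: %d subjects, threshold %.4g\n",
              length(x$cooks_d), x$threshold))
  if (length(x$flagged))
    cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  invisible(x)
}

#' Remove flagged subjects from a cohort
#'
#' Drops the subjects flagged by [cooks_distance_loo()] consistently from
#' every per-subject field of the cohort (moments, element densities, status,
#' aBMD analogue), preserving the order of the remaining subjects.
#'
#' @param cohort An `ssim_cohort` (or compatible list).
#' @param report An `outlier_report`, or an integer vector of indices.
#' @return The filtered cohort.  Removing all members of a class is an
#'   error.
#' @export
apply_exclusions <- function(cohort, report) {
  idx <- if (inherits(report, "outlier_report")) report$flagged
         else as.integer(report)
  N <- length(cohort$status)
  if (!length(idx)) return(cohort)
  if (any(idx < 1L | idx > N) || anyDuplicated(idx))
    stop("flagged indices out of range", call. = FALSE)
  keep <- setdiff(seq_len(N), idx)
  if (length(unique(cohort$status[keep])) < 2L)
    stop("exclusions would remove an entire class", call. = FALSE)
  cohort$moments <- cohort$moments[keep, , drop = FALSE]
  cohort$element_density <- cohort$element_density[keep, , drop = FALSE]
  cohort$status <- cohort$status[keep]
  cohort$abmd_analog <- cohort$abmd_analog[keep]
  if (!is.null(cohort$truth)) {
    cohort$truth$shape_scores <- cohort$truth$shape_scores[keep]
    cohort$truth$intensity_scores <- cohort$truth$intensity_scores[keep]
    cohort$truth$interaction_indicator <-
      cohort$truth$interaction_indicator[keep]
  }
  cohort
}
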