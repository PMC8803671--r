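# Balanced k-fold cross-validated fracture classification.
#
# For each fold the entire statistical model -- PLS mode extraction and, for
# the two-level shape-and-intensity model, both first-level models and the
# second-level fusion -- is rebuilt on the training subjects only; test
# subjects are projected through the trained modes and scored by a logistic
# model fitted on the training components.  Test-fold scores are pooled into
# one ROC curve (the per-model single-curve convention).

#' Fit a statistical model (SSM / SIM / SSIM / aBMD baseline) on a cohort
#'
#' @param cohort An `ssim_cohort` or compatible list (`moments`,
#'   `element_density`, `status`, `abmd_analog`).
#' @param model_kind One of `"SSM"`, `"SIM"`, `"SSIM"`, `"aBMD"`.
#' @param n_components Number of leading components used as logistic
#'   predictors (default 2; ignored for `"aBMD"`).
#' @param m_shape,m_int Optional explicit SSIM block sizes (see
#'   [fit_ssim()]; default 2 each).
#' @return A `stat_model`: list with the fitted PLS model(s), the logistic
#'   model on the leading components, and the predictor matrix used.
#' @export
fit_stat_model <- function(cohort, model_kind = c("SSM", "SIM", "SSIM",
                                                  "aBMD"),
                           n_components = 2L,
                           m_shape = NULL, m_int = NULL) {
  model_kind <- match.arg(model_kind)
  y <- as.numeric(cohort$status)
  nc <- as.integer(n_components)
  obj <- list(kind = model_kind, n_components = nc)
  if (model_kind == "SSM") {
    obj$pls <- fit_pls(cohort$moments, y, m = nc, id = "SSM")
    pred <- obj$pls$scores[, seq_len(nc), drop = FALSE]
  } else if (model_kind == "SIM") {
    obj$pls <- fit_pls(cohort$element_density, y, m = nc, id = "SIM")
    pred <- obj$pls$scores[, seq_len(nc), drop = FALSE]
  } else if (model_kind == "SSIM") {
    N <- length(y)
    ms <- as.integer(m_shape %||% 2L)
    mi <- as.integer(m_int %||% 2L)
    obj$ssm <- fit_pls(cohort$moments, y,
                       m = min(ms, N - 1L, ncol(cohort$moments)),
                       id = "SSM")
    obj$sim <- fit_pls(cohort$element_density, y,
                       m = min(mi, N - 1L, ncol(cohort$element_density)),
                       id = "SIM")
    obj$pls <- fit_ssim(obj$ssm, obj$sim, y,
                        m_shape = obj$ssm$n_modes, m_int = obj$sim$n_modes)
    nc <- min(nc, obj$pls$n_modes)
    obj$n_components <- nc
    pred <- obj$pls$scores[, seq_len(nc), drop = FALSE]
  } else {
    obj$n_components <- 1L
    pred <- matrix(cohort$abmd_analog, ncol = 1L,
                   dimnames = list(NULL, "abmd"))
  }
  obj$logistic <- fit_logistic(pred, y)
  obj$predictors <- pred
  structure(obj, class = "stat_model")
}

#' Score new subjects with a fitted statistical model
#'
#' Projects new subjects' shape/intensity data through the trained PLS modes
#' (including the two-level projection for the SSIM) and applies the trained
#' logistic model.  No refitting takes place.
#'
#' @param object A [fit_stat_model()] result.
#' @param cohort Cohort-like list holding the new subjects.
#' @param ... Unused.
#' @return Vector of predicted fracture probabilities.
#' @export
predict.stat_model <- function(object, cohort, ...) {
  nc <- object$n_components
  pred <- switch(object$kind,
    SSM = project_pls(object$pls, as.matrix(cohort$moments), m = nc),
    SIM = project_pls(object$pls, as.matrix(cohort$element_density), m = nc),
    SSIM = {
      bl <- object$pls$blocks
      Z <- cbind(project_pls(object$ssm, as.matrix(cohort$moments),
                             m = bl["shape"]),
                 project_pls(object$sim, as.matrix(cohort$element_density),
                             m = bl["intensity"]))
      project_pls(object$pls, Z, m = nc)
    },
    aBMD = matrix(cohort$abmd_analog, ncol = 1L))
  if (!is.matrix(pred))
    pred <- matrix(pred, ncol = object$logistic$n_predictors)
  predict(object$logistic, pred)
}

#' Cross-validated fracture risk classification
#'
#' Balanced stratified k-fold cross-validation of one of the four predictive
#' models: logistic regression on the first `n_components` PLS components of
#' the statistical shape model (SSM), intensity model (SIM) or two-level
#' shape-and-intensity model (SSIM), or on the areal-BMD analogue baseline.
#' Within each fold the full statistical model is rebuilt on training
#' subjects only and test subjects are projected, never refitted.  Pooled
#' test scores give the ROC curve, AUC, a stratified bootstrap 95% CI and
#' the confusion matrix at threshold 0.5.
#'
#' @param cohort An `ssim_cohort` or compatible list.
#' @param model_kind `"SSM"`, `"SIM"`, `"SSIM"` or `"aBMD"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving the fold assignment (and, offset by one,
#'   the bootstrap).
#' @param n_components Leading components used as predictors (default 2).
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000).
#' @param threshold Confusion-matrix decision threshold (default 0.5).
#' @param m_shape,m_int Passed to [fit_stat_model()] (SSIM block sizing).
#' @return A `cv_report`: list with `model_kind`, `fold_assignment`,
#'   `pooled_scores`, `roc_points`, `auc`, `auc_ci`, `confusion`,
#'   `per_fold_models` (the k logistic models), `k`, `seed`,
#'   `n_components`.
#' @export
#' @examples
#' coh <- sample_cohort(generator_config(n_subjects = 24, n_elements = 150,
#'                                       n_control_points = 27))
#' cross_validate(coh, "SIM", k = 4, seed = 1, n_boot = 200)$auc
cross_validate <- function(cohort, model_kind = c("SSM", "SIM", "SSIM",
                                                  "aBMD"),
                           k = 10L, seed = 1L, n_components = 2L,
                           n_boot = 2000L, threshold = 0.5,
                           m_shape = NULL, m_int = NULL) {
  model_kind <- match.arg(model_kind)
  y <- as.numeric(cohort$status)
  N <- length(y)
  folds <- stratified_kfold(y, k, seed)
  pooled <- rep(NA_real_, N)
  fold_models <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    te <- which(folds$fold_of == f)
    tr <- which(folds$fold_of != f)
    if (length(unique(y[tr])) < 2L)
      stop("training fold contains a single class", call. = FALSE)
    train <- .subset_cohort(cohort, tr)
    model <- fit_stat_model(train, model_kind, n_components = n_components,
                            m_shape = m_shape, m_int = m_int)
    pooled[te] <- predict(model, .subset_cohort(cohort, te))
    fold_models[[f]] <- model$logistic
  }
  ra <- roc_auc(pooled, y)
  structure(list(
    model_kind = model_kind,
    fold_assignment = folds,
    pooled_scores = pooled,
    roc_points = ra$roc_points,
    auc = ra$auc,
    auc_ci = auc_ci(pooled, y, n_boot = n_boot, seed = seed + 1L),
    confusion = confusion_at(pooled, y, threshold),
    per_fold_models = fold_models,
    k = folds$k, seed = as.integer(seed),
    n_components = as.integer(n_components)
  ), class = "cv_report")
}

.subset_cohort <- function(cohort, idx) {
  list(moments = cohort$moments[idx, , drop = FALSE],
       element_density = cohort$element_density[idx, , drop = FALSE],
       status = cohort$status[idx],
       abmd_analog = cohort$abmd_analog[idx])
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated %s classifier\n", x$k, x$model_kind))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat("  confusion matrix at threshold 0.5:\n")
  print(x$confusion)
  invisible(x)
}
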