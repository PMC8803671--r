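test_that("cross-validation reports are complete and internally
           consistent", {
  coh <- sample_cohort(generator_config(n_subjects = 24, n_elements = 150,
                                        n_control_points = 27, seed = 1))
  r <- cross_validate(coh, "SIM", k = 4, seed = 2, n_boot = 200)
  N <- length(coh$status)
  expect_equal(length(r$pooled_scores), N)
  expect_true(all(is.finite(r$pooled_scores)))
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_equal(sum(r$confusion), N)
  expect_length(r$per_fold_models, 4L)
  expect_true(all(diff(r$roc_points[, 1]) >= 0))
  expect_true(all(diff(r$roc_points[, 2]) >= 0))
  # deterministic given the seed
  r2 <- cross_validate(coh, "SIM", k = 4, seed = 2, n_boot = 200)
  expect_identical(r$pooled_scores, r2$pooled_scores)
  expect_identical(r$auc_ci, r2$auc_ci)
})

test_that("every model kind runs, including the aBMD baseline", {
  coh <- sample_cohort(generator_config(n_subjects = 24, n_elements = 150,
                                        n_control_points = 27, seed = 3))
  for (kind in c("SSM", "SIM", "SSIM", "aBMD")) {
    r <- cross_validate(coh, kind, k = 4, seed = 1, n_boot = 150)
    expect_s3_class(r, "cv_report")
    expect_true(is.finite(r$auc))
  }
})

test_that("statistical models are fitted on training subjects only
           (leakage guard)", {
  coh <- sample_cohort(generator_config(n_subjects = 30, n_elements = 150,
                                        n_control_points = 27, seed = 4))
  folds <- stratified_kfold(coh$status, 5, seed = 9)
  te <- which(folds$fold_of == 1)
  tr <- which(folds$fold_of != 1)
  sub <- function(idx) list(moments = coh$moments[idx, , drop = FALSE],
                            element_density =
                              coh$element_density[idx, , drop = FALSE],
                            status = coh$status[idx],
                            abmd_analog = coh$abmd_analog[idx])
  m_clean <- fit_stat_model(sub(tr), "SIM")
  # duplicating the test subjects into training MUST change the model and
  # its pooled scores; if test rows leaked in already, it could not
  m_leaky <- fit_stat_model(sub(c(tr, te)), "SIM")
  s_clean <- predict(m_clean, sub(te))
  s_leaky <- predict(m_leaky, sub(te))
  expect_false(isTRUE(all.equal(s_clean, s_leaky)))
  # and the fold models inside cross_validate equal the train-only fit
  r <- cross_validate(coh, "SIM", k = 5, seed = 9, n_boot = 150)
  expect_equal(unname(r$per_fold_models[[1]]$coefficients),
               unname(m_clean$logistic$coefficients), tolerance = 1e-10)
})

test_that("training folds with a single class are rejected", {
  coh <- sample_cohort(generator_config(n_subjects = 24, n_elements = 150,
                                        n_control_points = 27, seed = 5))
  expect_error(cross_validate(coh, "SIM", k = 20, seed = 1), "smaller class")
})

test_that("near-separable intensity cohorts reach high AUC", {
  cfg <- generator_config(n_subjects = 60, intensity_effect = 3,
                          shape_effect = 0, interaction_effect = 0,
                          noise_sd = 0.2, n_elements = 150,
                          n_control_points = 27, seed = 6)
  coh <- sample_cohort(cfg)
  r <- cross_validate(coh, "SIM", k = 5, seed = 1, n_boot = 150)
  expect_gt(r$auc, 0.95)
})

test_that("projection through a fitted stat model matches stored training
           components", {
  coh <- sample_cohort(generator_config(n_subjects = 24, n_elements = 150,
                                        n_control_points = 27, seed = 7))
  for (kind in c("SSM", "SIM", "SSIM")) {
    m <- fit_stat_model(coh, kind)
    p_train <- predict(m, coh)
    expect_equal(unname(p_train),
                 unname(predict(m$logistic, m$predictors)),
                 tolerance = 1e-8)
  }
})
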