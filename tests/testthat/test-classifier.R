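test_that("IRLS logistic matches an independent ML fit", {
  # small non-separable dataset; stats::glm is the independent solver
  set.seed(4)
  X <- matrix(rnorm(12), 6, 2)
  y <- c(0, 1, 0, 1, 1, 0)
  fit <- fit_logistic(X, y)
  oracle <- glm(y ~ X, family = binomial)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_equal(unname(predict(fit, X)),
               unname(fitted(oracle)), tolerance = 1e-6)

  # larger case, poorly scaled predictor (tiny variance, large mean)
  set.seed(5)
  n <- 80
  x1 <- 1.24 + rnorm(n, sd = 1e-4)
  y2 <- rbinom(n, 1, plogis(4e3 * (x1 - 1.24)))
  fit2 <- fit_logistic(cbind(x1), y2)
  oracle2 <- glm(y2 ~ x1, family = binomial)
  expect_equal(unname(fit2$coefficients), unname(coef(oracle2)),
               tolerance = 1e-4)
})

test_that("separation is detected and handled with a ridge fallback", {
  y <- c(0, 1, 0, 1, 0, 1)
  fit <- fit_logistic(matrix(y, 6, 1), y)
  expect_true(fit$separation)
  expect_equal(fit$ridge, 1e-4)
  expect_true(all(is.finite(fit$coefficients)))
  # the penalized fit still ranks the classes correctly
  p <- predict(fit, matrix(y, 6, 1))
  expect_true(all(p[y == 1] > p[y == 0]))
})

test_that("an all-zero predictor reduces to the null model", {
  y <- c(0, 1, 0, 1, 0, 1)
  fit <- fit_logistic(matrix(0, 6, 1), y)
  expect_equal(unname(fit$coefficients), c(qlogis(0.5), 0))
  y2 <- c(0, 0, 1, 1, 1, 1)
  fit2 <- fit_logistic(matrix(0, 6, 1), y2)
  expect_equal(unname(fit2$coefficients[1]), qlogis(2 / 3),
               tolerance = 1e-10)
  expect_error(fit_logistic(matrix(1:4, 4, 1), rep(1, 4)), "single class")
})

test_that("stratified folds are balanced, deterministic and seeded", {
  y <- rep(c(0, 1), c(47, 46))
  f <- stratified_kfold(y, k = 10, seed = 1)
  sizes <- table(f$fold_of)
  expect_true(all(sizes %in% 9:10))
  per_class <- table(f$fold_of, y)
  expect_true(all(per_class >= 4 & per_class <= 5))
  expect_identical(f, stratified_kfold(y, k = 10, seed = 1))
  expect_false(identical(f$fold_of,
                         stratified_kfold(y, k = 10, seed = 2)$fold_of))

  # leave-one-out degenerate case with balanced classes
  yb <- rep(c(0, 1), 5)
  floo <- stratified_kfold(yb, k = 5, seed = 3)
  expect_true(all(table(floo$fold_of) == 2))
  expect_error(stratified_kfold(yb, k = 6, seed = 1), "smaller class")
})

test_that("AUC equals brute-force pair counting with half ties", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  # worked example: 3 wins of 4 pairs
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(6)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    y <- rep_len(c(0, 1), n)[sample.int(n)]
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    expect_equal(roc_auc(s, y)$auc, brute(s, y))
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1) and AUC flips with
           labels", {
  set.seed(7)
  for (i in 1:20) {
    y <- rep_len(c(0, 1), 30)[sample.int(30)]
    s <- round(runif(30), 2)
    ra <- roc_auc(s, y)
    expect_equal(ra$roc_points[1, ], c(FPR = 0, TPR = 0))
    expect_equal(ra$roc_points[nrow(ra$roc_points), ],
                 c(FPR = 1, TPR = 1))
    expect_true(all(diff(ra$roc_points[, 1]) >= 0))
    expect_true(all(diff(ra$roc_points[, 2]) >= 0))
    expect_equal(roc_auc(s, 1 - y)$auc, 1 - ra$auc)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rep_len(c(0, 1), 40)[sample.int(40)]
  s <- round(runif(40), 1)
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("bootstrap CI is seeded, ordered and covers the point AUC", {
  set.seed(9)
  y <- rep_len(c(0, 1), 60)[sample.int(60)]
  s <- runif(60) + 0.5 * y
  ci <- auc_ci(s, y, n_boot = 500, seed = 5)
  expect_identical(ci, auc_ci(s, y, n_boot = 500, seed = 5))
  expect_lt(ci[1], ci[2])
  a <- roc_auc(s, y)$auc
  expect_true(ci[1] <= a && a <= ci[2])
  # perfect separation pins the upper bound at 1
  ci2 <- auc_ci(c(rep(0, 30), rep(1, 30)), rep(c(0, 1), c(30, 30)),
                n_boot = 200, seed = 1)
  expect_equal(ci2[2], 1)
  expect_error(auc_ci(s, y, n_boot = 10, seed = 1), "n_boot")
})

test_that("confusion matrices tally predictions at the threshold", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  cm <- confusion_at(s, y, threshold = 0.5)
  expect_equal(cm["fracture", "fracture"], 1)        # TP
  expect_equal(cm["fracture", "non-fracture"], 1)    # FN
  expect_equal(cm["non-fracture", "fracture"], 0)    # FP
  expect_equal(cm["non-fracture", "non-fracture"], 2)
  expect_equal(sum(cm), 4)
  cm2 <- confusion_at(y, y)
  expect_equal(unname(diag(cm2)), c(2, 2))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)
  cm3 <- confusion_at(rep(0, 4), y)
  expect_equal(unname(cm3[, "fracture"]), c(0, 0))   # nothing predicted positive
})
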