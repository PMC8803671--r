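test_that("the first NIPALS weight equals its closed form", {
  set.seed(1)
  for (rep in 1:10) {
    N <- sample(5:30, 1); p <- sample(3:20, 1)
    X <- matrix(rnorm(N * p), N, p)
    y <- rep_len(c(0, 1), N)[sample.int(N)]
    fit <- fit_pls(X, y, m = 1)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    w_oracle <- crossprod(Xc, yc); w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    if (w_oracle[which.max(abs(w_oracle))] < 0) w_oracle <- -w_oracle
    expect_equal(fit$weights[, 1], as.vector(w_oracle), tolerance = 1e-12)
  }
})

test_that("mode 1 maximises covariance with the response (dense search)", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c(0, 1), 20)
  fit <- fit_pls(X, y, m = 1)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  cov_at <- function(w) abs(sum((Xc %*% w) * yc))
  best <- cov_at(fit$weights[, 1])
  # dense unit-sphere search can never beat the fitted weight
  th <- seq(0, pi, length.out = 60)
  ph <- seq(0, 2 * pi, length.out = 120)
  grid <- cbind(rep(sin(th), times = length(ph)) *
                  cos(rep(ph, each = length(th))),
                rep(sin(th), times = length(ph)) *
                  sin(rep(ph, each = length(th))),
                rep(cos(th), times = length(ph)))
  sphere_cov <- abs(as.vector((grid %*% t(Xc)) %*% yc))
  expect_true(all(sphere_cov <= best + 1e-10))
})

test_that("signal columns attract the first weight", {
  set.seed(3)
  y <- rep(c(0, 1), 15)
  X <- cbind(y, matrix(rnorm(30 * 6, sd = 1), 30, 6))
  # orthogonalise noise columns against y to isolate the signal
  X[, -1] <- qr.resid(qr(cbind(1, y)), X[, -1])
  fit <- fit_pls(X, y, m = 1)
  expect_gt(abs(fit$weights[1, 1]), 0.999)
})

test_that("full-mode reconstruction reproduces the training data", {
  set.seed(4)
  N <- 15; p <- 8
  X <- matrix(rnorm(N * p), N, p)
  y <- rep_len(c(0, 1), N)
  fit <- fit_pls(X, y)      # m = min(N-1, p) = 8
  Xhat <- reconstruct(fit, fit$scores)
  expect_lt(rel_err(Xhat, X), 1e-8)
  # per-subject route
  expect_lt(rel_err(reconstruct(fit, fit$scores[3, ]), X[3, ]), 1e-8)
  # scores of successive modes are mutually orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  # variance-explained profiles are monotone and bounded
  expect_true(all(diff(fit$varexp_x) >= -1e-12))
  expect_true(all(fit$varexp_x <= 1 + 1e-8))
  expect_true(all(diff(fit$varexp_y) >= -1e-12))
  # column means are preserved through the reconstruction
  expect_equal(colMeans(Xhat), colMeans(X), tolerance = 1e-10)
})

test_that("reconstruction of zero components is the mean; +sigma/-sigma
           exports average back to the mean", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rep(c(0, 1), 10)
  fit <- fit_pls(X, y, m = 3)
  expect_equal(reconstruct(fit, c(0, 0, 0)), colMeans(X))
  s1 <- sqrt(fit$mode_variance[1])
  plus <- reconstruct(fit, c(s1, 0, 0))
  minus <- reconstruct(fit, c(-s1, 0, 0))
  expect_equal((plus + minus) / 2, colMeans(X), tolerance = 1e-12)
  expect_equal(plus, colMeans(X) + s1 * fit$loadings[, 1],
               tolerance = 1e-12)
})

test_that("projection is consistent with training scores and the mean", {
  set.seed(6)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- rep_len(c(0, 1), 25)
  fit <- fit_pls(X, y, m = 5)
  expect_equal(project_pls(fit, colMeans(X)), rep(0, 5),
               tolerance = 1e-10)
  expect_equal(project_pls(fit, X[7, ]), fit$scores[7, ],
               tolerance = 1e-8)
  expect_equal(project_pls(fit, X, m = 5), fit$scores, tolerance = 1e-8)
})

test_that("projecting a mean shift along mode 1 returns the shift", {
  # rank-1 data: single latent direction, so loadings and weights align
  set.seed(7)
  u <- rnorm(12); u <- u / sqrt(sum(u^2))
  t_true <- rnorm(30) + rep(c(0, 1), 15)
  X <- outer(t_true, u)
  y <- rep(c(0, 1), 15)
  fit <- fit_pls(X, y, m = 1)
  x_new <- colMeans(X) + 2 * fit$loadings[, 1]
  expect_equal(project_pls(fit, x_new)[1], 2, tolerance = 1e-8)
})

test_that("PLS contract errors are raised", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10)), "single class")
  expect_error(fit_pls(X, rep(c(0, 1), 5), m = 12), "between 1 and")
  fit <- fit_pls(X, rep(c(0, 1), 5), m = 2)
  expect_error(reconstruct(fit, c(1, 2, 3)), "more components")
  expect_error(project_pls(fit, rnorm(5)), "dimension")
})

test_that("zero cross-covariance stops extraction early with a flag", {
  # X orthogonal to y by construction: first weight is undefined
  y <- rep(c(0, 1), 10)
  X <- matrix(rep(seq_len(20), 2), 20, 2)  # columns constant across classes
  X <- qr.resid(qr(cbind(1, y)), X)
  expect_error(fit_pls(X * 0, y), "zero cross-covariance")
  # rank-limited data: extraction stops at the rank with the flag set
  u <- rnorm(6)
  X1 <- outer(c(rnorm(20)) + y, u)
  fit <- fit_pls(X1, y)
  expect_true(fit$early_stop)
  expect_equal(fit$n_modes, 1L)
})

test_that("modes_to_explain reads the variance profiles", {
  fit <- list(varexp_x = c(0.5, 0.8, 0.92), varexp_y = c(0.7, 0.9, 0.95),
              n_modes = 3L)
  expect_equal(as.integer(modes_to_explain(fit, 0.9)), 3L)
  expect_equal(as.integer(modes_to_explain(fit, 0.5)), 1L)
  expect_equal(as.integer(modes_to_explain(fit, 0.9, on = "y")), 2L)
  unreached <- modes_to_explain(fit, 0.99)
  expect_equal(as.integer(unreached), 3L)
  expect_false(attr(unreached, "reached"))
  expect_error(modes_to_explain(fit, 1.2), "target_fraction")
})

test_that("two-level SSIM weights follow the informative block", {
  set.seed(9)
  N <- 200   # large N keeps spurious in-sample noise correlation small
  y <- rep(c(0, 1), N / 2)
  # intensity block carries all the signal, shape block is pure noise
  sim_X <- cbind(y + rnorm(N, sd = 0.1), matrix(rnorm(N * 3), N))
  ssm_X <- matrix(rnorm(N * 4), N)
  ssm <- fit_pls(ssm_X, y, m = 2)
  sim <- fit_pls(sim_X, y, m = 2)
  ssim <- fit_ssim(ssm, sim, y, m_shape = 2, m_int = 2)
  w1 <- ssim$weights[, 1]
  int_mass <- sum(w1[3:4]^2) / sum(w1^2)
  expect_gt(int_mass, 0.9)
  expect_equal(unname(ssim$blocks), c(2L, 2L))

  # duplicated identical blocks: symmetric first-mode weights
  dup <- fit_ssim(sim, sim, y, m_shape = 2, m_int = 2)
  w <- dup$weights[, 1]
  expect_equal(w[1:2], w[3:4], tolerance = 1e-8)

  # degenerate block sizes are contract errors
  expect_error(fit_ssim(ssm, sim, y, m_shape = 0, m_int = 2),
               "at least one")
  expect_error(fit_ssim(ssm, sim, y, m_shape = 5, m_int = 2),
               "more component columns")
})

test_that("mode exports decode through the deformation model", {
  tpl <- small_template()
  coh <- sample_cohort(small_config(seed = 12))
  ssm <- fit_pls(coh$moments, coh$status, m = 2, id = "SSM")
  f_plus <- export_mode_shapes(ssm, tpl, 1, scale = 1, what = "shape",
                               file = tempfile(fileext = ".ply"))
  f_minus <- export_mode_shapes(ssm, tpl, 1, scale = -1, what = "shape",
                                file = tempfile(fileext = ".ply"))
  vp <- attr(f_plus, "decoded")$vertices
  vm <- attr(f_minus, "decoded")$vertices
  # +sigma and -sigma surfaces average to the mean-shape surface
  mean_surf <- deform(tpl$surface$vertices, tpl$grid,
                      moment_field(ssm$mean))
  expect_equal((vp + vm) / 2, mean_surf, tolerance = 1e-8)
  # scale 0 is the mean decoded exactly
  f0 <- export_mode_shapes(ssm, tpl, 1, scale = 0, what = "shape",
                           file = tempfile(fileext = ".ply"))
  expect_equal(attr(f0, "decoded")$vertices, mean_surf, tolerance = 1e-10)
  expect_error(export_mode_shapes(ssm, tpl, 9), "out of range")
  expect_true(file.exists(f_plus))

  # hand computation on a 2-control-point fixture
  g2 <- control_grid(rbind(c(0, 0, 0), c(2, 0, 0)), kernel_width = 1.5)
  fake <- list(surface = list(vertices = matrix(c(1, 0, 0), 1, 3),
                              faces = matrix(c(1, 1, 1), 1, 3)),
               tet = tpl$tet, grid = g2)
  model <- ssm
  model$mean <- rep(0, 6)
  model$scale_sd <- rep(1, 6)
  model$loadings <- matrix(0, 6, 2)
  model$loadings[, 1] <- c(1, 0, 0, 0, 3, 0) / sqrt(10)
  model$mode_variance <- c(10, 1)
  out <- export_mode_shapes(model, fake, 1, scale = 1, what = "shape",
                            file = tempfile(fileext = ".ply"))
  w <- exp(-1 / 1.5^2)
  expect_equal(as.vector(attr(out, "decoded")$vertices),
               c(1 + w * 1, w * 3, 0), tolerance = 1e-12)
})
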