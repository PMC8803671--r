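test_that("kernel deformation matches hand-computed displacements", {
  # single control point, coincident query point: kernel value 1
  g <- control_grid(matrix(0, 1, 3), kernel_width = 1)
  out <- deform(matrix(0, 1, 3), g, c(1, 0, 0))
  expect_equal(as.vector(out), c(1, 0, 0))

  # zero moments: no deformation
  tpl <- small_template()
  expect_equal(deform(tpl$surface$vertices, tpl$grid,
                      matrix(0, 27, 3)),
               tpl$surface$vertices)

  # two control points, one query point: Gaussian-weighted sum by hand
  g2 <- control_grid(rbind(c(0, 0, 0), c(2, 0, 0)), kernel_width = 1.5)
  beta <- rbind(c(1, 0, 0), c(0, 3, 0))
  x <- matrix(c(1, 0, 0), 1, 3)
  w1 <- exp(-1 / 1.5^2); w2 <- exp(-1 / 1.5^2)
  expect_equal(as.vector(deform(x, g2, beta)),
               c(1 + w1 * 1, w2 * 3, 0), tolerance = 1e-14)
})

test_that("deformation is exactly linear in the moments", {
  tpl <- small_template()
  set.seed(5)
  b1 <- matrix(rnorm(27 * 3), ncol = 3)
  b2 <- matrix(rnorm(27 * 3), ncol = 3)
  x <- tpl$surface$vertices
  d1 <- deform(x, tpl$grid, b1) - x
  d2 <- deform(x, tpl$grid, b2) - x
  d12 <- deform(x, tpl$grid, 2.5 * b1 - 0.7 * b2) - x
  expect_equal(d12, 2.5 * d1 - 0.7 * d2, tolerance = 1e-12)
})

test_that("moment flattening follows the documented row-major order", {
  B <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(flatten_moments(B), c(1, 2, 3, 4, 5, 6))
  expect_equal(unclass(moment_field(c(1, 2, 3, 4, 5, 6))), B)
  expect_error(moment_field(1:4), "multiple of 3")
  expect_error(moment_field(c(1, NA, 3)), "finite")
})

test_that("fit_moments inverts deform in the small-deformation regime", {
  tpl <- small_template()
  bstar <- smooth_moments(tpl, seed = 21)
  subj <- deform(tpl$surface$vertices, tpl$grid, bstar)
  bhat <- fit_moments(tpl$surface$vertices, subj, tpl$grid,
                      reg_lambda = 1e-8)
  expect_lt(rel_err(unclass(bhat), bstar), 0.05)

  # template to itself: moments stay at zero
  b0 <- fit_moments(tpl$surface$vertices, tpl$surface$vertices, tpl$grid)
  expect_lt(sqrt(sum(unclass(b0)^2)), 1e-8)

  # doubling the true moments doubles the recovered ones (forward model
  # is linear; correspondence stays exact in this regime)
  subj2 <- deform(tpl$surface$vertices, tpl$grid, 2 * bstar)
  bhat2 <- fit_moments(tpl$surface$vertices, subj2, tpl$grid,
                       reg_lambda = 1e-8)
  expect_lt(rel_err(unclass(bhat2), 2 * unclass(bhat)), 0.01)
})

test_that("shape matrices assemble and round-trip moment fields", {
  set.seed(8)
  fields <- lapply(1:3, function(i) moment_field(matrix(rnorm(6), 2, 3)))
  X <- build_shape_matrix(fields, subject_ids = c("a", "b", "c"))
  expect_equal(dim(X), c(3L, 6L))
  expect_equal(rownames(X), c("a", "b", "c"))
  expect_equal(unclass(moment_field(X[2, ])), unclass(fields[[2]]),
               ignore_attr = TRUE)
  # mixed grids are a hard error
  bad <- c(fields, list(moment_field(matrix(0, 3, 3))))
  expect_error(build_shape_matrix(bad), "q mismatch")
})

test_that("whole-cohort rigid motions leave the shape matrix unchanged", {
  tpl <- small_template()
  grid <- tpl$grid
  betas <- lapply(c(31, 32), function(s) smooth_moments(tpl, seed = s))
  subjects <- lapply(betas, function(b)
    deform(tpl$surface$vertices, grid, b))
  fit_one <- function(subj) {
    unclass(fit_moments(tpl$surface$vertices, subj, grid,
                        reg_lambda = 1e-8))
  }
  X_ref <- do.call(rbind, lapply(lapply(subjects, fit_one),
                                 flatten_moments))
  # move every input by one global rigid motion, then align back
  R <- rot_z(0.4); tv <- c(10, -5, 2)
  X_mov <- do.call(rbind, lapply(subjects, function(s) {
    moved <- sweep(s %*% t(R), 2, tv, `+`)
    res <- icp_align(moved, s)   # vertex sets correspond exactly
    flatten_moments(fit_one(apply_transform(res$transform, moved)))
  }))
  expect_lt(max(abs(X_mov - X_ref)), 1e-4)
})
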