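test_that("generator configuration validates its invariants", {
  expect_error(generator_config(n_subjects = 3), "n_subjects")
  expect_error(generator_config(class_balance = 0), "class_balance")
  expect_error(generator_config(n_subjects = 10, class_balance = 0.01),
               "empty class")
  expect_error(generator_config(n_control_points = 30), "perfect cube")
  expect_error(generator_config(shape_effect = -1), "effect sizes")
  expect_error(generator_config(noise_sd = 0), "noise_sd")
})

test_that("identical configurations give bitwise-identical cohorts", {
  c1 <- sample_cohort(small_config(seed = 42))
  c2 <- sample_cohort(small_config(seed = 42))
  expect_identical(c1, c2)
  c3 <- sample_cohort(small_config(seed = 43))
  expect_false(identical(c1$moments, c3$moments))
})

test_that("cohort fields are mutually consistent", {
  cfg <- small_config(seed = 7)
  coh <- sample_cohort(cfg)
  N <- cfg$n_subjects
  expect_equal(length(coh$status), N)
  expect_true(all(coh$status %in% c(0L, 1L)))
  expect_equal(sum(coh$status), cfg$n_fractured)
  expect_equal(nrow(coh$moments), N)
  expect_equal(ncol(coh$moments), 3L * cfg$n_control_points)
  expect_equal(dim(coh$element_density),
               c(N, nrow(coh$template$tet$elems)))
  expect_true(all(coh$element_density >= 0))
  expect_equal(length(coh$abmd_analog), N)
  expect_true(all(coh$abmd_analog > 0))
})

test_that("class-conditional mean shift along the latent direction is the
           configured effect size (law of large numbers)", {
  cfg <- generator_config(n_subjects = 2000, shape_effect = 0,
                          intensity_effect = 5, interaction_effect = 0,
                          noise_sd = 0.1, n_elements = 100,
                          n_control_points = 27, seed = 9)
  coh <- sample_cohort(cfg)
  proj <- as.vector(coh$element_density %*% coh$truth$v_int)
  diff <- mean(proj[coh$status == 0]) - mean(proj[coh$status == 1])
  expect_lt(abs(diff - 5) / 5, 0.1)
})

test_that("with all effects zero the classes are exchangeable", {
  cfg <- small_config(seed = 3, shape_effect = 0, intensity_effect = 0,
                      interaction_effect = 0)
  coh <- sample_cohort(cfg)
  # status must be independent of the data: the latent scores carry no
  # class shift
  a <- coh$truth$shape_scores; b <- coh$truth$intensity_scores
  expect_equal(mean(a[coh$status == 1]) - mean(a[coh$status == 0]), 0,
               tolerance = 2)   # ~N(0, sd ~ 0.45); sanity, not power
  expect_true(all(abs(c(a, b)) < 6))
})

test_that("areal projection matches hand arithmetic", {
  cube <- box_tet_mesh()
  # uniform 1000 mg/cm^3 over the unit cube: mass 1000 * 1 cm^3, shadow
  # 1 cm^2 -> 1 g/cm^2
  expect_equal(areal_projection(rep(1000, 6), cube), 1.0)
  # exact linearity in density
  d <- runif(6, 100, 900)
  expect_equal(areal_projection(2 * d, cube),
               2 * areal_projection(d, cube))
  # two-element fixture with hand-set volumes and a supplied area:
  # tets (0,e1,e2,e3) and (e1+e2+e3 opposite corner) each of volume 1/6
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1))
  mesh <- structure(list(nodes = nodes,
                         elems = rbind(c(1L, 2L, 3L, 4L),
                                       c(5L, 4L, 3L, 2L))),
                    class = "tet_mesh")
  v <- tet_volumes(mesh)
  expect_equal(v, c(1 / 6, 1 / 3), tolerance = 1e-12)
  got <- areal_projection(c(600, 300), mesh, projected_area = 2)
  expect_equal(got, (600 * 1 / 6 + 300 * 1 / 3) / 2 * 1e-3)
  expect_error(areal_projection(c(1, 2), mesh, projected_area = 0),
               "zero")
  expect_error(areal_projection(1:5, cube), "one value per element")
})

test_that("matrix input to areal_projection maps rows to subjects", {
  cube <- box_tet_mesh()
  D <- rbind(rep(1000, 6), rep(500, 6))
  expect_equal(areal_projection(D, cube), c(1.0, 0.5))
})
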