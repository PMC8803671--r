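# Shared fixtures: small, fast configurations used across test files.

small_config <- function(seed = 1L, ...) {
  generator_config(n_subjects = 20L, n_elements = 150L,
                   n_control_points = 27L, seed = seed, ...)
}

# cached small template (deterministic, so safe to share)
small_template <- local({
  tpl <- NULL
  function() {
    if (is.null(tpl)) tpl <<- make_template(small_config())
    tpl
  }
})

# relative Frobenius / l2 error
rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# a smooth moment field in the identifiable range of the kernel model,
# scaled so the maximum surface displacement is `max_disp` (mm)
smooth_moments <- function(template, seed, max_disp = 1.5) {
  grid <- template$grid
  G <- exp(-as.matrix(dist(grid$points))^2 / grid$kernel_width^2)
  Z <- withr::with_seed(seed,
    matrix(rnorm(nrow(grid$points) * 3, sd = 0.1), ncol = 3))
  B <- G %*% Z
  disp <- deform(template$surface$vertices, grid, B) -
    template$surface$vertices
  B * max_disp / max(abs(disp))
}

# independent Kabsch solution (closed form), used as an ICP oracle
kabsch_oracle <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cq - as.vector(R %*% cp))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
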