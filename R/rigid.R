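# Rigid transforms and alignment: anatomical initialisation (head centre +
# neck-shaft axis) followed by point-to-point ICP with the Kabsch update.

#' Rigid transform constructor
#'
#' Represents the map `x -> R x + t`.
#'
#' @param R 3 x 3 rotation matrix.
#' @param t Length-3 translation.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper rotation", call. = FALSE)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(points) %*% t(transform$R), 2, transform$t, `+`)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$R),
                  -as.vector(t(transform$R) %*% transform$t))
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

# rotation taking unit vector u onto unit vector v by the minimal angle;
# for anti-parallel vectors the rotation axis is `fallback` (projected
# perpendicular to u), or a documented coordinate-axis rule if degenerate
.rotation_between <- function(u, v, fallback = NULL) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # anti-parallel: rotate by pi about a perpendicular axis; prefer the
    # fallback direction, else the first coordinate axis not parallel to u
    perp <- NULL
    if (!is.null(fallback)) {
      perp <- fallback - sum(fallback * u) * u
      if (sqrt(sum(perp^2)) < 1e-9) perp <- NULL
    }
    if (is.null(perp)) {
      for (e in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        perp <- e - sum(e * u) * u
        if (sqrt(sum(perp^2)) > 1e-6) break
      }
    }
    perp <- perp / sqrt(sum(perp^2))
    return(2 * tcrossprod(perp) - diag(3))
  }
  ax <- ax / s
  .axis_angle(ax, atan2(s, c_))
}

.axis_angle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Anatomical initial alignment
#'
#' Computes the rigid transform taking a subject surface onto a reference
#' surface from their anatomical annotations alone: head centres are
#' superposed exactly, neck axes are aligned by the minimal rotation, and the
#' residual roll about the neck axis is resolved by aligning the projections
#' of the shaft axes onto the plane perpendicular to the neck axis.  For
#' anti-parallel neck axes the flip axis is the component of the reference
#' shaft axis perpendicular to the neck axis (coordinate axes as a last
#' resort).
#'
#' @param subject,reference Surfaces carrying `head_centre`, `neck_axis` and
#'   `shaft_axis` entries (as produced by [make_template()]).
#' @return A [rigid_transform()] mapping subject coordinates into the
#'   reference frame.
#' @export
initial_align <- function(subject, reference) {
  need <- c("head_centre", "neck_axis", "shaft_axis")
  for (nm in need) {
    if (is.null(subject[[nm]]))
      stop("subject surface lacks annotation '", nm, "'", call. = FALSE)
    if (is.null(reference[[nm]]))
      stop("reference surface lacks annotation '", nm, "'", call. = FALSE)
  }
  R1 <- .rotation_between(subject$neck_axis, reference$neck_axis,
                          fallback = reference$shaft_axis)
  # roll about the reference neck axis to align shaft-axis projections
  n <- reference$neck_axis / sqrt(sum(reference$neck_axis^2))
  s_ref <- reference$shaft_axis - sum(reference$shaft_axis * n) * n
  s_sub <- as.vector(R1 %*% subject$shaft_axis)
  s_sub <- s_sub - sum(s_sub * n) * n
  R2 <- diag(3)
  if (sqrt(sum(s_ref^2)) > 1e-9 && sqrt(sum(s_sub^2)) > 1e-9) {
    s_ref <- s_ref / sqrt(sum(s_ref^2))
    s_sub <- s_sub / sqrt(sum(s_sub^2))
    cr <- c(s_sub[2] * s_ref[3] - s_sub[3] * s_ref[2],
            s_sub[3] * s_ref[1] - s_sub[1] * s_ref[3],
            s_sub[1] * s_ref[2] - s_sub[2] * s_ref[1])
    theta <- atan2(sum(cr * n), sum(s_sub * s_ref))
    R2 <- .axis_angle(n, theta)
  }
  R <- R2 %*% R1
  t <- reference$head_centre - as.vector(R %*% subject$head_centre)
  rigid_transform(R, t)
}

#' Least-squares rigid fit between corresponding point sets (Kabsch)
#'
#' @param source,target `n x 3` matrices of corresponding points.
#' @return The [rigid_transform()] minimising
#'   `sum(|R source_i + t - target_i|^2)`, with the SVD determinant
#'   correction enforcing a proper rotation.
#' @export
rigid_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3)
  ps <- colMeans(source); pt <- colMeans(target)
  H <- crossprod(sweep(source, 2, ps), sweep(target, 2, pt))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, pt - as.vector(R %*% ps))
}

# index of the nearest row of `target` for every row of `query`
nearest_neighbours <- function(query, target) {
  tt <- rowSums(target^2)
  d2 <- outer(rowSums(query^2), tt, `+`) - 2 * tcrossprod(query, target)
  max.col(-d2, ties.method = "first")
}

#' Iterative closest point rigid registration
#'
#' Standard point-to-point ICP: nearest-neighbour correspondence from the
#' transformed source to the target, least-squares rigid update by
#' [rigid_fit()], iterated until the mean-squared correspondence distance
#' improves by less than `tol` or `max_iter` is reached.  Non-convergence
#' returns the best transform found so far with `converged = FALSE` and a
#' warning (not an error).
#'
#' @param source,target `n x 3` point matrices, at least 4 non-coplanar
#'   points each.
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the mean-squared-distance improvement.
#' @param init Optional initial [rigid_transform()].
#' @return List with `transform`, `rmsd`, `n_iter`, `converged`.
#' @export
icp_align <- function(source, target, max_iter = 50L, tol = 1e-10,
                      init = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 4L || nrow(target) < 4L)
    stop("ICP needs at least 4 points on each side", call. = FALSE)
  tf <- init %||% rigid_transform()
  cur <- apply_transform(tf, source)
  msd_prev <- Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    nn <- nearest_neighbours(cur, target)
    corr <- target[nn, , drop = FALSE]
    upd <- rigid_fit(cur, corr)
    tf <- compose_transforms(upd, tf)
    cur <- apply_transform(tf, source)
    msd <- mean(rowSums((cur - target[nearest_neighbours(cur, target), ,
                                      drop = FALSE])^2))
    if (msd_prev - msd < tol) { converged <- TRUE; break }
    msd_prev <- msd
    if (it >= max_iter) break
  }
  if (!converged)
    warning("ICP did not converge within max_iter; returning best so far")
  list(transform = tf, rmsd = sqrt(msd), n_iter = it, converged = converged)
}
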