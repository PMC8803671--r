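# Gaussian-kernel small-deformation model on a shared control-point grid.
#
# A subject shape is encoded by one moment vector beta_k per control point
# c_k; a point x is carried to
#     x + sum_k exp(-|x - c_k|^2 / w^2) beta_k,
# which is exactly linear in the moments.  Applying the same deformation to
# the template surface and to the template tetrahedral mesh yields
# iso-topological subject meshes.  Flattening order of a moment field is
# row-major per control point: (bx1, by1, bz1, ..., bxq, byq, bzq).

#' Moment field constructor
#'
#' @param beta Either a `q x 3` matrix of per-control-point moment vectors or
#'   a length-`3q` vector in the documented flattening order
#'   `(bx1, by1, bz1, ..., bxq, byq, bzq)`.
#' @param q Number of control points (required when `beta` is a flat vector
#'   of ambiguous length; inferred otherwise).
#' @return A `moment_field`: `q x 3` matrix with class attribute.
#' @export
moment_field <- function(beta, q = NULL) {
  if (is.matrix(beta) && ncol(beta) == 3L) {
    m <- beta
  } else {
    beta <- as.numeric(beta)
    if (length(beta) %% 3L != 0L)
      stop("flat moment vector length must be a multiple of 3", call. = FALSE)
    q_inf <- length(beta) %/% 3L
    if (!is.null(q) && q != q_inf)
      stop("moment vector length does not match q", call. = FALSE)
    m <- matrix(beta, ncol = 3L, byrow = TRUE)
  }
  if (any(!is.finite(m))) stop("moment vectors must be finite", call. = FALSE)
  structure(unname(m), class = "moment_field")
}

#' Flatten a moment field to the documented row-major order
#' @param beta A [moment_field()] or `q x 3` matrix.
#' @return Length-`3q` numeric vector `(bx1, by1, bz1, ...)`.
#' @export
flatten_moments <- function(beta) as.vector(t(unclass(beta)))

# Gaussian kernel matrix between points (n x 3) and grid control points
kernel_matrix <- function(points, grid) {
  stopifnot(inherits(grid, "control_grid"))
  points <- as.matrix(points)
  d2 <- outer(rowSums(points^2), rowSums(grid$points^2), `+`) -
    2 * tcrossprod(points, grid$points)
  exp(-pmax(d2, 0) / grid$kernel_width^2)
}

#' Deform points by a moment field
#'
#' @param points `n x 3` matrix of points to deform (e.g. template surface
#'   vertices or tetrahedral mesh nodes).
#' @param grid A [control_grid()].
#' @param beta A [moment_field()], `q x 3` matrix, or flat length-`3q`
#'   vector.
#' @return Deformed `n x 3` matrix.  The map is exactly linear in `beta`.
#' @export
#' @examples
#' g <- control_grid(matrix(0, 1, 3), kernel_width = 1)
#' deform(matrix(0, 1, 3), g, c(1, 0, 0))  # unit displacement
deform <- function(points, grid, beta) {
  B <- unclass(moment_field(beta, q = nrow(grid$points)))
  if (nrow(B) != nrow(grid$points))
    stop("moment field size does not match the control grid", call. = FALSE)
  as.matrix(points) + kernel_matrix(points, grid) %*% B
}

#' Default ridge regularisation for moment fitting
#'
#' `1e-6` times the trace of the control-grid kernel Gram matrix (which is
#' exactly `q`, since the kernel is 1 at distance zero): a scale-free
#' conditioning floor.
#'
#' @param grid A [control_grid()].
#' @return Scalar ridge penalty.
#' @export
default_reg_lambda <- function(grid) 1e-6 * nrow(grid$points)

#' Fit moment vectors carrying the template onto a subject surface
#'
#' Alternates (a) nearest-neighbour vertex-to-vertex correspondence from the
#' currently deformed template to the subject surface and (b) a
#' ridge-regularised linear least-squares solve for the moments minimising
#' `sum |deform(v) - corresp(v)|^2 + reg_lambda |beta|^2`.  Stops when the
#' mean-squared displacement update falls below `tol` or after `max_iter`
#' sweeps.  Deterministic given its inputs.  The subject is assumed to be
#' pre-aligned (see [initial_align()] and [icp_align()]).
#'
#' @param template_points `n x 3` template surface vertices.
#' @param subject_points `m x 3` aligned subject surface vertices.
#' @param grid A [control_grid()].
#' @param max_iter Maximum alternation sweeps (default 30).
#' @param tol Stop when the mean-squared change of the fitted displacement
#'   field falls below this (default 1e-10).
#' @param reg_lambda Ridge penalty; default [default_reg_lambda()].  A value
#'   of exactly 0 with a singular normal system raises an error instructing
#'   to increase it.
#' @return A [moment_field()] with attributes `rmsd` (final
#'   correspondence root-mean-square distance) and `n_iter`.
#' @export
fit_moments <- function(template_points, subject_points, grid,
                        max_iter = 30L, tol = 1e-10, reg_lambda = NULL) {
  template_points <- as.matrix(template_points)
  subject_points <- as.matrix(subject_points)
  lambda <- reg_lambda %||% default_reg_lambda(grid)
  K <- kernel_matrix(template_points, grid)
  KtK <- crossprod(K)
  q <- nrow(grid$points)
  A <- KtK + diag(lambda, q)
  B <- matrix(0, q, 3L)
  disp_prev <- matrix(0, nrow(template_points), 3L)
  it <- 0L
  rmsd <- NA_real_
  repeat {
    it <- it + 1L
    cur <- template_points + K %*% B
    nn <- nearest_neighbours(cur, subject_points)
    D <- subject_points[nn, , drop = FALSE] - template_points
    B <- tryCatch(solve(A, crossprod(K, D)), error = function(e)
      stop("normal system is singular; raise reg_lambda above ",
           format(lambda), call. = FALSE))
    disp <- K %*% B
    delta <- mean((disp - disp_prev)^2)
    rmsd <- sqrt(mean(rowSums((template_points + disp -
                               subject_points[nn, , drop = FALSE])^2)))
    if (delta < tol || it >= max_iter) break
    disp_prev <- disp
  }
  out <- moment_field(B)
  attr(out, "rmsd") <- rmsd
  attr(out, "n_iter") <- it
  out
}

#' Assemble the shape matrix from per-subject moment fields
#'
#' Row `i` holds subject `i`'s flattened moment field in the documented
#' order, giving the `N x 3q` shape matrix that the statistical shape model
#' is fitted to.
#'
#' @param moment_fields List of [moment_field()] objects sharing one control
#'   grid size.
#' @param subject_ids Optional character vector of subject identifiers.
#' @return `N x 3q` numeric matrix with `subject_ids` as row names when
#'   given.
#' @export
build_shape_matrix <- function(moment_fields, subject_ids = NULL) {
  if (!length(moment_fields)) stop("no moment fields given", call. = FALSE)
  qs <- vapply(moment_fields, function(b) nrow(unclass(b)), integer(1))
  if (length(unique(qs)) != 1L)
    stop("moment fields use different control grids (q mismatch)",
         call. = FALSE)
  X <- do.call(rbind, lapply(moment_fields, flatten_moments))
  if (!is.null(subject_ids)) {
    stopifnot(length(subject_ids) == nrow(X))
    rownames(X) <- subject_ids
  }
  X
}
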