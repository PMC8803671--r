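# NIPALS PLS1 mode extraction.
#
# For a column-centered data matrix X and centered binary response y, each
# mode j extracts
#     w_j = X_j' y_j / |X_j' y_j|        (weight: direction of maximal
#                                         covariance with the response)
#     t_j = X_j w_j                      (component / score)
#     p_j = X_j' t_j / (t_j' t_j)        (x-loading / mode)
#     q_j = y_j' t_j / (t_j' t_j)        (y-loading)
# followed by deflation X_{j+1} = X_j - t_j p_j', y_{j+1} = y_j - q_j t_j.
# Successive components are mutually orthogonal and the full set reconstructs
# the centered data exactly: x^i = xbar + sum_j t_j^i p_j.

#' Fit a PLS1 model of a data matrix against fracture status
#'
#' NIPALS partial least squares with a single (binary) response: extracts
#' modes of maximal covariance between the rows of `X` (shape moments,
#' element densities, or concatenated component blocks) and the fracture
#' status array.  Columns are centered; by default they are not variance
#' scaled (shape and intensity blocks each carry homogeneous units).
#'
#' @param X `N x p` numeric matrix.
#' @param y Length-`N` response with both classes present (0 = non-fracture,
#'   1 = fracture).
#' @param m Number of modes to extract; default and maximum
#'   `min(N - 1, p)`.  Extraction stops early (with `early_stop = TRUE`)
#'   if the residual cross-covariance vanishes.
#' @param scale Logical; variance-scale columns before fitting (default
#'   `FALSE`).  Constant columns are left unscaled.
#' @param id Optional label stored on the model.
#' @return A `pls_model`: list with `mean` (column means), `weights`
#'   (`p x m`), `loadings` (`p x m` modes `p_j`), `scores` (`N x m`
#'   components `t_j`), `y_loadings`, `mode_variance` (`var(t_j)`),
#'   `varexp_x` and `varexp_y` (cumulative fractions of data / response
#'   variance explained), `n_modes`, `early_stop`, `scale` information.
#'   Sign convention: each weight vector is flipped so that its
#'   largest-magnitude entry is positive.
#' @export
#' @examples
#' X <- cbind(rep(c(0, 1), 5), matrix(rnorm(40), 10))
#' fit <- fit_pls(X, rep(c(0, 1), 5), m = 2)
#' fit$varexp_y
fit_pls <- function(X, y, m = NULL, scale = FALSE, id = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X); p <- ncol(X)
  if (N < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (length(y) != N) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("response contains a single class; PLS against fracture status ",
         "requires both classes", call. = FALSE)
  m_max <- min(N - 1L, p)
  m <- as.integer(m %||% m_max)
  if (m < 1L || m > m_max)
    stop(sprintf("m must be between 1 and min(N-1, p) = %d", m_max),
         call. = FALSE)

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sds <- rep(1, p)
  if (scale) {
    sds <- apply(Xc, 2, sd)
    sds[sds == 0] <- 1
    Xc <- sweep(Xc, 2, sds, `/`)
  }
  ybar <- mean(y)
  yc <- y - ybar
  ss_x <- sum(Xc^2)
  ss_y <- sum(yc^2)

  W <- matrix(0, p, m); P <- matrix(0, p, m); TT <- matrix(0, N, m)
  qv <- numeric(m); vx <- numeric(m); vy <- numeric(m)
  Xd <- Xc; yd <- yc
  early <- FALSE
  j <- 0L
  tol0 <- 1e-12 * max(1, sqrt(sum(crossprod(Xc, yc)^2)))
  while (j < m) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < tol0) { early <- TRUE; break }
    w <- w / nw
    # sign convention: largest-magnitude weight entry positive
    if (w[which.max(abs(w))] < 0) w <- -w
    tj <- as.vector(Xd %*% w)
    tt <- sum(tj^2)
    if (tt < 1e-24) { early <- TRUE; break }
    pj <- crossprod(Xd, tj) / tt
    qj <- sum(yd * tj) / tt
    Xd <- Xd - tcrossprod(tj, pj)
    yd <- yd - qj * tj
    j <- j + 1L
    W[, j] <- w; P[, j] <- pj; TT[, j] <- tj; qv[j] <- qj
    vx[j] <- tt * sum(pj^2)
    vy[j] <- qj^2 * tt
  }
  if (j == 0L)
    stop("zero cross-covariance between X and the status array; no modes ",
         "extractable", call. = FALSE)
  keep <- seq_len(j)
  structure(list(
    mean = mu,
    weights = W[, keep, drop = FALSE],
    loadings = P[, keep, drop = FALSE],
    scores = TT[, keep, drop = FALSE],
    y_loadings = qv[keep],
    y_mean = ybar,
    mode_variance = apply(TT[, keep, drop = FALSE], 2, var),
    varexp_x = cumsum(vx[keep]) / ss_x,
    varexp_y = cumsum(vy[keep]) / ss_y,
    n_modes = j,
    early_stop = early,
    scale = scale,
    scale_sd = sds,
    id = id
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS1 model%s: %d modes over %d variables (%d subjects)\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$n_modes, length(x$mean), nrow(x$scores)))
  k <- min(4L, x$n_modes)
  cat(sprintf("  varexp (data):    %s\n",
              paste(sprintf("%.3f", x$varexp_x[1:k]), collapse = " ")))
  cat(sprintf("  varexp (status):  %s\n",
              paste(sprintf("%.3f", x$varexp_y[1:k]), collapse = " ")))
  if (x$early_stop) cat("  (extraction stopped early: cross-covariance exhausted)\n")
  invisible(x)
}

#' Reconstruct a data vector from PLS components
#'
#' Implements `x = xbar + sum_j t_j p_j` over the leading modes.
#'
#' @param model A [fit_pls()] model.
#' @param components Length-`m` component vector (or `N x m` matrix of
#'   rows), `m` at most `model$n_modes`.
#' @return Reconstructed vector (or matrix) on the original data scale.
#' @export
reconstruct <- function(model, components) {
  comp <- if (is.matrix(components)) components
          else matrix(components, nrow = 1L)
  m <- ncol(comp)
  if (m > model$n_modes)
    stop("more components than fitted modes", call. = FALSE)
  out <- tcrossprod(comp, model$loadings[, seq_len(m), drop = FALSE])
  out <- sweep(out, 2, model$scale_sd, `*`)
  out <- sweep(out, 2, model$mean, `+`)
  if (!is.matrix(components)) out[1, ] else out
}

#' Project new data onto a fitted PLS model
#'
#' Sequential NIPALS projection with deflation: for each mode,
#' `t_j = e' w_j` and `e <- e - t_j p_j` starting from the centered new
#' vector.  Projecting a training row returns its stored components.
#'
#' @param model A [fit_pls()] model.
#' @param x_new Length-`p` vector or `n x p` matrix of new observations.
#' @param m Number of components to return (default all fitted modes).
#' @return Length-`m` vector (or `n x m` matrix) of components.
#' @export
project_pls <- function(model, x_new, m = NULL) {
  m <- as.integer(m %||% model$n_modes)
  stopifnot(m >= 1L, m <= model$n_modes)
  E <- if (is.matrix(x_new)) x_new else matrix(x_new, nrow = 1L)
  if (ncol(E) != length(model$mean))
    stop("x_new dimension does not match the model", call. = FALSE)
  E <- sweep(E, 2, model$mean)
  E <- sweep(E, 2, model$scale_sd, `/`)
  TT <- matrix(0, nrow(E), m)
  for (j in seq_len(m)) {
    tj <- as.vector(E %*% model$weights[, j])
    TT[, j] <- tj
    E <- E - tcrossprod(tj, model$loadings[, j])
  }
  if (!is.matrix(x_new)) TT[1, ] else TT
}

#' Two-level shape-and-intensity PLS model
#'
#' Concatenates the leading shape and intensity PLS component columns into
#' one matrix and fits a second-level PLS against fracture status, giving the
#' statistical shape-and-intensity model (SSIM).  Block provenance of the
#' input columns is retained for interpretation.
#'
#' @param ssm,sim [fit_pls()] models fitted on the same subjects in the same
#'   order (shape and intensity respectively).
#' @param y The fracture status array used for both.
#' @param m_shape,m_int Numbers of component columns taken from each model
#'   (>= 1).  Default: 2 per block (capped by the fitted mode count).
#'   Because every PLS mode is extracted to covary with the status array,
#'   trailing modes chase residual noise; concatenating many of them
#'   overfits the second level at cohort-scale N, so the default keeps only
#'   the leading components of each block.
#' @param m Number of second-level modes (default `min(N-1, m_shape+m_int)`).
#' @return A `pls_model` with additional class `ssim_model` and a `blocks`
#'   field `c(shape = m_shape, intensity = m_int)`.
#' @export
fit_ssim <- function(ssm, sim, y, m_shape = NULL, m_int = NULL, m = NULL) {
  stopifnot(inherits(ssm, "pls_model"), inherits(sim, "pls_model"))
  if (nrow(ssm$scores) != nrow(sim$scores))
    stop("shape and intensity models were fitted on different numbers of ",
         "subjects", call. = FALSE)
  m_shape <- as.integer(m_shape %||% min(2L, ssm$n_modes))
  m_int <- as.integer(m_int %||% min(2L, sim$n_modes))
  if (m_shape < 1L || m_int < 1L)
    stop("each block must contribute at least one component column",
         call. = FALSE)
  if (m_shape > ssm$n_modes || m_int > sim$n_modes)
    stop("requested more component columns than fitted modes", call. = FALSE)
  Z <- cbind(ssm$scores[, seq_len(m_shape), drop = FALSE],
             sim$scores[, seq_len(m_int), drop = FALSE])
  colnames(Z) <- c(paste0("shape", seq_len(m_shape)),
                   paste0("int", seq_len(m_int)))
  out <- fit_pls(Z, y, m = m, id = "SSIM")
  out$blocks <- c(shape = m_shape, intensity = m_int)
  class(out) <- c("ssim_model", class(out))
  out
}

#' Number of modes needed to explain a variance fraction
#'
#' @param model A [fit_pls()] model.
#' @param target_fraction Fraction in (0, 1).
#' @param on `"x"` for data variance (default) or `"y"` for fracture-status
#'   variance.
#' @return Smallest mode count whose cumulative explained variance reaches
#'   the target; if unreachable with the fitted modes, the fitted mode count
#'   with attribute `reached = FALSE`.
#' @export
modes_to_explain <- function(model, target_fraction, on = c("x", "y")) {
  on <- match.arg(on)
  if (!is.finite(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1)
    stop("target_fraction must lie in (0, 1)", call. = FALSE)
  prof <- if (on == "x") model$varexp_x else model$varexp_y
  hit <- which(prof >= target_fraction)
  if (length(hit)) {
    out <- hit[1]
    attr(out, "reached") <- TRUE
  } else {
    out <- model$n_modes
    attr(out, "reached") <- FALSE
  }
  out
}

#' Export a mode as a deformed template / element field
#'
#' Decodes `xbar + scale * sigma_j * p_j` of mode `j` back to the physical
#' representation: a deformed surface mesh for a shape model (written as
#' ASCII PLY), an element density field on the template tetrahedral mesh for
#' an intensity model (written as legacy ASCII VTK), or both for a two-level
#' shape-and-intensity model (decoded through its first-level models).
#' `sigma_j` is the mode standard deviation `sqrt(var(t_j))`.
#'
#' @param model A [fit_pls()] model.
#' @param template A [make_template()] object (provides the surface, the
#'   tetrahedral mesh and the control grid).
#' @param j Mode index.
#' @param scale Multiple of `sigma_j` to move along the mode (e.g. `-1`,
#'   `+1`; `0` exports the mean itself).
#' @param what `"shape"` or `"intensity"`; chosen automatically for
#'   single-block models whose dimension matches, required meaning for raw
#'   use.
#' @param ssm,sim First-level models; required for `ssim_model` input.
#' @param file Output path; defaults to a tempfile with the right extension.
#' @return The path of the written file, invisibly; the decoded object is
#'   attached as attribute `decoded` (surface list or density vector).
#' @export
export_mode_shapes <- function(model, template, j, scale = 1,
                               what = c("shape", "intensity"),
                               ssm = NULL, sim = NULL, file = NULL) {
  if (j < 1L || j > model$n_modes) stop("mode index out of range",
                                        call. = FALSE)
  sig <- sqrt(model$mode_variance[j])
  if (inherits(model, "ssim_model")) {
    if (is.null(ssm) || is.null(sim))
      stop("exporting an SSIM mode needs the first-level ssm and sim models",
           call. = FALSE)
    comp <- model$mean + scale * sig * model$loadings[, j]
    bl <- model$blocks
    beta_vec <- reconstruct(ssm, comp[seq_len(bl["shape"])])
    dens <- reconstruct(sim, comp[bl["shape"] + seq_len(bl["intensity"])])
    surf <- template$surface
    surf$vertices <- deform(surf$vertices, template$grid,
                            moment_field(beta_vec))
    file <- file %||% tempfile(fileext = ".vtk")
    ply <- sub("\\.vtk$", ".ply", file)
    write_ply(surf, ply)
    tet <- template$tet
    tet$nodes <- deform(tet$nodes, template$grid, moment_field(beta_vec))
    write_vtk_tet(tet, file, cell_data = list(density = as.vector(dens)))
    out <- file
    attr(out, "decoded") <- list(surface = surf, density = as.vector(dens))
    return(invisible(out))
  }
  what <- match.arg(what)
  x <- reconstruct(model, ((seq_len(model$n_modes) == j) * scale * sig
                           )[seq_len(model$n_modes)])
  if (what == "shape") {
    surf <- template$surface
    surf$vertices <- deform(surf$vertices, template$grid, moment_field(x))
    file <- file %||% tempfile(fileext = ".ply")
    write_ply(surf, file)
    out <- file
    attr(out, "decoded") <- surf
  } else {
    file <- file %||% tempfile(fileext = ".vtk")
    write_vtk_tet(template$tet, file,
                  cell_data = list(density = as.vector(x)))
    out <- file
    attr(out, "decoded") <- as.vector(x)
  }
  invisible(out)
}
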