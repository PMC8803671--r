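# Stylized proximal-femur template geometry and structured tetrahedral meshing.
#
# The template is an implicit solid: a vertical shaft cylinder, an angled neck
# cylinder and an offset head sphere.  It is meshed by voxelising its bounding
# box and splitting every inside cube into the six Kuhn tetrahedra (all sharing
# the cube's main diagonal), which is conforming across neighbouring cubes
# without any parity bookkeeping.  The surface is the set of boundary faces of
# the tetrahedral mesh, oriented outward.

# geometry constants (mm); neck-shaft angle ~130 degrees
.femur_geometry <- function() {
  ang <- 50 * pi / 180
  neck_axis <- c(0, sin(ang), cos(ang))
  neck_start <- c(0, 0, 60)
  head_centre <- neck_start + 45 * neck_axis
  list(shaft_radius = 14, shaft_length = 70,
       neck_radius = 10, neck_length = 45,
       neck_start = neck_start, neck_axis = neck_axis,
       head_radius = 22, head_centre = head_centre,
       shaft_axis = c(0, 0, 1))
}

# vectorized inside test for the implicit femur solid; pts is n x 3
.femur_inside <- function(pts, geom = .femur_geometry()) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  in_shaft <- (x^2 + y^2 <= geom$shaft_radius^2) &
    z >= 0 & z <= geom$shaft_length
  d <- sweep(pts, 2, geom$neck_start)
  s <- as.vector(d %*% geom$neck_axis)
  perp2 <- rowSums(d^2) - s^2
  in_neck <- perp2 <= geom$neck_radius^2 & s >= 0 & s <= geom$neck_length
  h <- sweep(pts, 2, geom$head_centre)
  in_head <- rowSums(h^2) <= geom$head_radius^2
  in_shaft | in_neck | in_head
}

# Kuhn decomposition of the unit cube: 6 tetrahedra sharing the 000-111
# diagonal, one per permutation of the axes; vertex ids refer to the corner
# ordering (i, j, k) in {0,1}^3 listed as 1 + i + 2j + 4k.  Orientation fixed
# so all signed volumes are positive.
.kuhn_tets <- local({
  corner_id <- function(v) 1L + v[1] + 2L * v[2] + 4L * v[3]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  out <- matrix(0L, 6, 4)
  for (t in seq_along(perms)) {
    pm <- perms[[t]]
    v0 <- c(0, 0, 0)
    v1 <- v0; v1[pm[1]] <- 1
    v2 <- v1; v2[pm[2]] <- 1
    v3 <- c(1, 1, 1)
    ids <- c(corner_id(v0), corner_id(v1), corner_id(v2), corner_id(v3))
    a <- corners[ids[1], ]; b <- corners[ids[2], ]
    cc <- corners[ids[3], ]; d <- corners[ids[4], ]
    vol <- det(cbind(b - a, cc - a, d - a)) / 6
    if (vol < 0) ids <- ids[c(1, 3, 2, 4)]
    out[t, ] <- ids
  }
  out
})

#' Structured tetrahedral mesh of an axis-aligned box
#'
#' Splits a box into `nx * ny * nz` cubes and each cube into six Kuhn
#' tetrahedra with consistently positive signed volumes.  Used both as the
#' meshing primitive of [make_template()] and as a convenient fixture builder.
#'
#' @param lower,upper Numeric length-3 box corners.
#' @param n Integer length-3 cell counts per axis.
#' @param keep Optional predicate taking an `m x 3` matrix of cell centres and
#'   returning a logical vector; only cells with `TRUE` are meshed.
#' @return A `tet_mesh`: list with `nodes` (`n x 3`) and `elems` (`m x 4`
#'   1-based node indices, positively oriented).
#' @export
box_tet_mesh <- function(lower = c(0, 0, 0), upper = c(1, 1, 1),
                         n = c(1L, 1L, 1L), keep = NULL) {
  n <- as.integer(rep_len(n, 3L))
  if (any(n < 1L)) stop("cell counts must be >= 1", call. = FALSE)
  h <- (upper - lower) / n
  if (any(h <= 0)) stop("upper must exceed lower on every axis", call. = FALSE)
  cells <- as.matrix(expand.grid(i = seq_len(n[1]) - 1L,
                                 j = seq_len(n[2]) - 1L,
                                 k = seq_len(n[3]) - 1L))
  if (!is.null(keep)) {
    centres <- sweep(sweep(cells + 0.5, 2, h, `*`), 2, lower, `+`)
    cells <- cells[keep(centres), , drop = FALSE]
    if (nrow(cells) == 0L)
      stop("no mesh cells remain inside the solid; refine the resolution",
           call. = FALSE)
  }
  # global corner lattice ids: corner (i,j,k), 0-based, on (n+1) lattice
  np <- n + 1L
  lat_id <- function(i, j, k) 1L + i + np[1] * (j + np[2] * k)
  used <- integer(0)
  elems <- matrix(0L, nrow = 6L * nrow(cells), ncol = 4L)
  row <- 0L
  corner_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (c_i in seq_len(nrow(cells))) {
    base <- cells[c_i, ]
    ids8 <- lat_id(base[1] + corner_off[, 1],
                   base[2] + corner_off[, 2],
                   base[3] + corner_off[, 3])
    for (t in 1:6) {
      row <- row + 1L
      elems[row, ] <- ids8[.kuhn_tets[t, ]]
    }
  }
  used <- sort(unique(as.vector(elems)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  elems[] <- remap[elems]
  u0 <- used - 1L
  k_idx <- u0 %/% (np[1] * np[2])
  j_idx <- (u0 %% (np[1] * np[2])) %/% np[1]
  i_idx <- u0 %% np[1]
  nodes <- cbind(lower[1] + i_idx * h[1],
                 lower[2] + j_idx * h[2],
                 lower[3] + k_idx * h[3])
  colnames(nodes) <- c("x", "y", "z")
  structure(list(nodes = nodes, elems = elems), class = "tet_mesh")
}

#' Signed volumes of tetrahedral elements
#'
#' @param mesh A `tet_mesh`.
#' @return Numeric vector of signed volumes (positive under the package's
#'   consistent node ordering).
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  a <- nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 2], , drop = FALSE] - a
  cc <- nd[el[, 3], , drop = FALSE] - a
  d <- nd[el[, 4], , drop = FALSE] - a
  (b[, 1] * (cc[, 2] * d[, 3] - cc[, 3] * d[, 2]) -
   b[, 2] * (cc[, 1] * d[, 3] - cc[, 3] * d[, 1]) +
   b[, 3] * (cc[, 1] * d[, 2] - cc[, 2] * d[, 1])) / 6
}

# centroids of tetrahedral elements, m x 3
tet_centroids <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  (nd[el[, 1], , drop = FALSE] + nd[el[, 2], , drop = FALSE] +
   nd[el[, 3], , drop = FALSE] + nd[el[, 4], , drop = FALSE]) / 4
}

# Boundary surface of a tet mesh: faces belonging to exactly one element,
# oriented so normals point away from the opposite vertex (outward).
.tet_boundary_surface <- function(mesh) {
  el <- mesh$elems
  face_local <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  opp_local <- c(1, 2, 3, 4)
  faces <- NULL; opps <- NULL
  for (f in 1:4) {
    faces <- rbind(faces, el[, face_local[f, ], drop = FALSE])
    opps <- c(opps, el[, opp_local[f]])
  }
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  tab <- table(key)
  bnd <- which(key %in% names(tab)[tab == 1L])
  bfaces <- faces[bnd, , drop = FALSE]
  bopp <- opps[bnd]
  nd <- mesh$nodes
  a <- nd[bfaces[, 1], , drop = FALSE]
  ab <- nd[bfaces[, 2], , drop = FALSE] - a
  ac <- nd[bfaces[, 3], , drop = FALSE] - a
  nrm <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
               ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
               ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  # swap two vertices wherever the normal points toward the opposite vertex
  inward <- rowSums(nrm * (nd[bopp, , drop = FALSE] - a)) > 0
  bfaces[inward, ] <- bfaces[inward, c(1, 3, 2), drop = FALSE]
  used <- sort(unique(as.vector(bfaces)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  list(vertices = nd[used, , drop = FALSE],
       faces = matrix(remap[bfaces], ncol = 3))
}

#' Regular control-point lattice over a bounding box
#'
#' @param lower,upper Length-3 box corners.
#' @param q Number of control points; must be a perfect cube `k^3`, giving a
#'   `k` x `k` x `k` lattice whose extreme points are exactly the box corners.
#' @param kernel_width Gaussian kernel width (same length unit as the box);
#'   defaults to twice the mean lattice spacing.
#' @return A `control_grid`: list with `points` (`q x 3`) and `kernel_width`.
#' @export
regular_control_grid <- function(lower, upper, q, kernel_width = NULL) {
  k <- as.integer(round(q^(1 / 3)))
  if (k^3 != q) stop("q must be a perfect cube", call. = FALSE)
  axes <- lapply(1:3, function(a)
    if (k == 1L) mean(c(lower[a], upper[a]))
    else seq(lower[a], upper[a], length.out = k))
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  spacing <- if (k > 1L) mean((upper - lower) / (k - 1)) else
    mean(upper - lower)
  control_grid(pts, kernel_width %||% (2 * spacing))
}

#' Control grid constructor
#'
#' @param points `q x 3` matrix of control point coordinates (mm).
#' @param kernel_width Positive Gaussian kernel width (mm).
#' @return A `control_grid` object.
#' @export
control_grid <- function(points, kernel_width) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L)
    stop("points must be a q x 3 matrix with q >= 1", call. = FALSE)
  if (anyDuplicated(points)) stop("control points must be distinct",
                                  call. = FALSE)
  if (!is.finite(kernel_width) || kernel_width <= 0)
    stop("kernel_width must be > 0", call. = FALSE)
  structure(list(points = unname(points), kernel_width = kernel_width),
            class = "control_grid")
}

#' Build the synthetic template meshes and control grid
#'
#' Constructs the stylized proximal-femur template playing the role of the
#' population mean shape: a closed, consistently oriented triangulated
#' surface, a tetrahedral mesh of the interior with at least
#' `0.8 * n_elements` positively oriented elements, and a regular
#' control-point lattice covering the mesh bounding box.  Fully deterministic
#' for a given configuration.
#'
#' The surface carries the anatomical annotations needed by
#' [initial_align()]: the femoral head centre and the neck and shaft axes.
#'
#' @param config A [generator_config()].
#' @return A `femur_template`: list with `surface` (vertices, faces,
#'   `head_centre`, `neck_axis`, `shaft_axis`), `tet` (a `tet_mesh`) and
#'   `grid` (a `control_grid`).
#' @export
#' @examples
#' tpl <- make_template(generator_config(n_elements = 150))
#' nrow(tpl$tet$elems) >= 0.8 * 150
make_template <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  geom <- .femur_geometry()
  pad <- 1e-6
  lower <- c(-geom$head_radius, -geom$shaft_radius,
             0) - c(1, 1, 1) * pad
  upper <- c(geom$head_radius,
             geom$head_centre[2] + geom$head_radius,
             geom$head_centre[3] + geom$head_radius) + pad
  # deterministic volume estimate on a fixed probe lattice
  probe <- as.matrix(expand.grid(
    seq(lower[1], upper[1], length.out = 40),
    seq(lower[2], upper[2], length.out = 40),
    seq(lower[3], upper[3], length.out = 40)))
  vol_est <- mean(.femur_inside(probe, geom)) * prod(upper - lower)
  target <- config$n_elements
  h <- (6 * vol_est / target)^(1 / 3)
  mesh <- NULL
  for (attempt in 1:6) {
    n_cells <- pmax(1L, as.integer(ceiling((upper - lower) / h)))
    mesh <- tryCatch(
      box_tet_mesh(lower, lower + n_cells * h, n_cells,
                   keep = function(p) .femur_inside(p, geom)),
      error = function(e) NULL)
    if (!is.null(mesh) && nrow(mesh$elems) >= 0.8 * target) break
    h <- h * 0.85
  }
  if (is.null(mesh) || nrow(mesh$elems) < 0.8 * target)
    stop(sprintf(paste0("template meshing failed: could not reach %d elements",
                        " (n_elements=%d, final spacing %.3g mm)"),
                 ceiling(0.8 * target), target, h), call. = FALSE)
  vols <- tet_volumes(mesh)
  if (any(vols <= 0))
    stop(sprintf("template meshing produced %d degenerate tetrahedra at spacing %.3g mm",
                 sum(vols <= 0), h), call. = FALSE)
  surf <- .tet_boundary_surface(mesh)
  surf$head_centre <- geom$head_centre
  surf$neck_axis <- geom$neck_axis
  surf$shaft_axis <- geom$shaft_axis
  bb_lo <- apply(mesh$nodes, 2, min)
  bb_hi <- apply(mesh$nodes, 2, max)
  grid <- regular_control_grid(bb_lo, bb_hi, config$n_control_points)
  structure(list(surface = surf, tet = mesh, grid = grid,
                 spacing = h),
            class = "femur_template")
}

#' @export
print.femur_template <- function(x, ...) {
  cat(sprintf(paste0("Stylized femur template: %d surface vertices / %d faces, ",
                     "%d tet nodes / %d elements, %d control points\n"),
              nrow(x$surface$vertices), nrow(x$surface$faces),
              nrow(x$tet$nodes), nrow(x$tet$elems), nrow(x$grid$points)))
  invisible(x)
}
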