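# Intensity pipeline: phantom calibration, element-wise density sampling on
# the (morphed) tetrahedral mesh, and assembly of the intensity matrix G.

#' Fit the phantom calibration line
#'
#' Ordinary least squares of known phantom densities on measured image
#' intensities: `density = slope * intensity + intercept`.  Standard use is
#' the five-sample hydroxyapatite phantom spanning 0-200 mg/cm^3.
#'
#' @param phantom_intensities Measured intensities (>= 2 distinct values).
#' @param phantom_densities Known densities (mg/cm^3), same length.
#' @return A `calibration_line`: list with `slope` (mg/cm^3 per intensity
#'   unit), `intercept` (mg/cm^3), `r2`.
#' @export
#' @examples
#' fit_calibration(0:4, c(0, 50, 100, 150, 200))  # slope 50, intercept 0
fit_calibration <- function(phantom_intensities, phantom_densities) {
  x <- as.numeric(phantom_intensities)
  y <- as.numeric(phantom_densities)
  if (length(x) != length(y) || length(x) < 2L)
    stop("need matched intensity/density samples (>= 2)", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("all phantom intensities identical; calibration line undefined",
         call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  ssr <- sum((y - slope * x - intercept)^2)
  sst <- sum(yc^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(slope = slope, intercept = intercept, r2 = r2),
            class = "calibration_line")
}

#' Identity calibration (intensities already in mg/cm^3)
#' @return A `calibration_line` with slope 1, intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(slope = 1, intercept = 0, r2 = 1),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration: density = %.6g * intensity + %.6g (r2 = %.4f)\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Map a scalar intensity field onto element densities
#'
#' Samples the subject's intensity field on the (morphed) tetrahedral mesh
#' and applies the calibration line, giving one density value per element in
#' template element order.  The field is aggregated per element either at
#' the centroid (default) or as the mean over the four nodes and the
#' centroid.  Negative calibrated densities are clamped to 0; the clamp
#' count is recorded in attribute `n_clamped`.
#'
#' @param field Function mapping an `n x 3` coordinate matrix to intensity
#'   values; must be defined over the whole mesh (NA/NaN returns are a hard
#'   error listing the offending element ids).
#' @param tet_mesh A `tet_mesh` (the template mesh morphed onto the
#'   subject).
#' @param calibration A [fit_calibration()] line; default identity.
#' @param rule `"centroid"` or `"mean5"`.
#' @return Numeric density vector (mg/cm^3), one entry per element, with
#'   attribute `n_clamped`.
#' @export
map_element_density <- function(field, tet_mesh,
                                calibration = identity_calibration(),
                                rule = c("centroid", "mean5")) {
  rule <- match.arg(rule)
  stopifnot(is.function(field))
  cents <- tet_centroids(tet_mesh)
  vals <- if (rule == "centroid") {
    field(cents)
  } else {
    nd <- tet_mesh$nodes; el <- tet_mesh$elems
    (field(nd[el[, 1], , drop = FALSE]) +
     field(nd[el[, 2], , drop = FALSE]) +
     field(nd[el[, 3], , drop = FALSE]) +
     field(nd[el[, 4], , drop = FALSE]) +
     field(cents)) / 5
  }
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("intensity field undefined over elements: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "", call. = FALSE)
  dens <- calibration$slope * vals + calibration$intercept
  n_clamped <- sum(dens < 0)
  dens[dens < 0] <- 0
  attr(dens, "n_clamped") <- n_clamped
  dens
}

#' Assemble the intensity matrix G
#'
#' Stacks per-subject element density vectors into the `N x n` intensity
#' matrix, enforcing the iso-topology contract: every subject must carry
#' exactly one value per template element.
#'
#' @param vectors List of density vectors of equal length.
#' @param subject_ids Optional identifiers used in error messages and row
#'   names.
#' @return `N x n` numeric matrix.
#' @export
build_intensity_matrix <- function(vectors, subject_ids = NULL) {
  if (!length(vectors)) stop("no intensity vectors given", call. = FALSE)
  ids <- subject_ids %||% as.character(seq_along(vectors))
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("iso-topology violation: subject ", ids[bad], " has ", lens[bad],
         " elements but subject ", ids[1], " has ", lens[1], call. = FALSE)
  }
  G <- do.call(rbind, lapply(vectors, as.numeric))
  if (!is.null(subject_ids)) rownames(G) <- subject_ids
  G
}
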