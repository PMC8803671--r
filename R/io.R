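# Plain-text file interfaces: ASCII PLY surfaces, legacy ASCII VTK
# tetrahedral meshes with optional element fields, headered delimited
# matrices, and whole-cohort round trips with a JSON sidecar.

#' Write a triangulated surface as ASCII PLY
#'
#' Anatomical annotations (`head_centre`, `neck_axis`, `shaft_axis`), when
#' present, are stored as PLY comment lines and recovered by [read_ply()].
#'
#' @param surface List with `vertices` (`n x 3`) and `faces` (`m x 3`,
#'   1-based).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path) {
  v <- as.matrix(surface$vertices); f <- as.matrix(surface$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0"), con)
  for (nm in c("head_centre", "neck_axis", "shaft_axis"))
    if (!is.null(surface[[nm]]))
      writeLines(sprintf("comment %s %.17g %.17g %.17g", nm,
                         surface[[nm]][1], surface[[nm]][2],
                         surface[[nm]][3]), con)
  writeLines(c(sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
  invisible(path)
}

#' Read an ASCII PLY surface written by [write_ply()]
#' @param path File path.
#' @return Surface list (`vertices`, `faces`, plus any stored annotations).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  hdr_end <- match("end_header", lines)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", hdr, value = TRUE)))
  out <- list()
  for (cm in grep("^comment ", hdr, value = TRUE)) {
    parts <- strsplit(cm, " +")[[1]]
    if (length(parts) == 5L && parts[2] %in%
        c("head_centre", "neck_axis", "shaft_axis"))
      out[[parts[2]]] <- as.numeric(parts[3:5])
  }
  vtx <- matrix(scan(text = lines[hdr_end + seq_len(nv)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  fc <- matrix(scan(text = lines[hdr_end + nv + seq_len(nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)
  if (any(fc[, 1] != 3)) stop("only triangulated PLY supported",
                              call. = FALSE)
  out$vertices <- vtx
  faces <- fc[, 2:4, drop = FALSE] + 1
  storage.mode(faces) <- "integer"
  out$faces <- faces
  out
}

#' Write a tetrahedral mesh as legacy ASCII VTK
#'
#' @param mesh A `tet_mesh`.
#' @param path Output path.
#' @param cell_data Optional named list of per-element scalar fields.
#' @return `path`, invisibly.
#' @export
write_vtk_tet <- function(mesh, path, cell_data = NULL) {
  nd <- as.matrix(mesh$nodes); el <- as.matrix(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nd))), con)
  writeLines(sprintf("%.17g %.17g %.17g", nd[, 1], nd[, 2], nd[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(el), 5L * nrow(el)), con)
  writeLines(sprintf("4 %d %d %d %d", el[, 1] - 1L, el[, 2] - 1L,
                     el[, 3] - 1L, el[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep("10", nrow(el)), con)
  if (!is.null(cell_data) && length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nrow(el)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK tetrahedral mesh written by [write_vtk_tet()]
#' @param path File path.
#' @return A `tet_mesh`, with any scalar element fields in attribute
#'   `cell_data`.
#' @export
read_vtk_tet <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  np <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nodes <- matrix(scan(text = lines[ip + seq_len(np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS ", lines)[1]
  nc <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- matrix(scan(text = lines[ic + seq_len(nc)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4)) stop("only tetrahedral cells supported",
                                 call. = FALSE)
  elems <- cells[, 2:5, drop = FALSE] + 1
  storage.mode(elems) <- "integer"
  mesh <- structure(list(nodes = nodes, elems = elems),
                    class = "tet_mesh")
  icd <- grep("^CELL_DATA ", lines)
  if (length(icd)) {
    fields <- list()
    isc <- grep("^SCALARS ", lines)
    for (s in isc[isc > icd[1]]) {
      nm <- strsplit(lines[s], " +")[[1]][2]
      fields[[nm]] <- scan(text = lines[s + 1L + seq_len(nc)], quiet = TRUE)
    }
    attr(mesh, "cell_data") <- fields
  }
  mesh
}

#' Write a matrix as headered delimited text
#'
#' First line: `# rows=N cols=p kind=<kind>`; then one comma-separated row
#' per subject.
#'
#' @param x Numeric matrix (or vector, written as one column).
#' @param path Output path.
#' @param kind One of `"shape"`, `"intensity"`, `"components"`, `"status"`,
#'   `"abmd"`.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(x, path,
                             kind = c("shape", "intensity", "components",
                                      "status", "abmd")) {
  kind <- match.arg(kind)
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d cols=%d kind=%s", nrow(x), ncol(x), kind),
             con)
  writeLines(apply(x, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = ",")), con)
  invisible(path)
}

#' Read a headered delimited matrix written by [write_matrix_txt()]
#'
#' Validates the header against the file body; dimension mismatches,
#' truncated rows and unknown headers are hard errors naming the offending
#' file and row.
#'
#' @param path File path.
#' @param expect_kind Optional kind the header must declare.
#' @return Numeric matrix with attribute `kind`.
#' @export
read_matrix_txt <- function(path, expect_kind = NULL) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr,
    regexec("^# rows=(\\d+) cols=(\\d+) kind=(\\w+)$", hdr))[[1]]
  if (length(m) != 4L)
    stop("unknown header in ", path, ": '", hdr, "'", call. = FALSE)
  nr <- as.integer(m[2]); ncols <- as.integer(m[3]); kind <- m[4]
  if (!is.null(expect_kind) && kind != expect_kind)
    stop(path, ": header kind '", kind, "' but expected '", expect_kind,
         "'", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != nr)
    stop(path, ": header announces ", nr, " rows but file has ",
         length(body), call. = FALSE)
  rows <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(rows)
  bad <- which(lens != ncols)
  if (length(bad))
    stop(path, ": truncated or ragged row ", bad[1], " (", lens[bad[1]],
         " of ", ncols, " values)", call. = FALSE)
  out <- matrix(as.numeric(unlist(rows)), nrow = nr, byrow = TRUE)
  if (anyNA(out))
    stop(path, ": non-numeric entries present", call. = FALSE)
  attr(out, "kind") <- kind
  out
}

#' Write a cohort to a directory
#'
#' Writes `moments.csv`, `element_density.csv`, `status.csv`, `abmd.csv`
#' (headered delimited text), the template surface (`template_surface.ply`)
#' and tetrahedral mesh (`template_volume.vtk`), and a `cohort.json` sidecar
#' recording the generator configuration and the latent truth.
#'
#' @param cohort An `ssim_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_txt(cohort$moments, file.path(dir, "moments.csv"), "shape")
  write_matrix_txt(cohort$element_density,
                   file.path(dir, "element_density.csv"), "intensity")
  write_matrix_txt(as.numeric(cohort$status), file.path(dir, "status.csv"),
                   "status")
  write_matrix_txt(cohort$abmd_analog, file.path(dir, "abmd.csv"), "abmd")
  if (!is.null(cohort$template)) {
    write_ply(cohort$template$surface,
              file.path(dir, "template_surface.ply"))
    write_vtk_tet(cohort$template$tet,
                  file.path(dir, "template_volume.vtk"))
    grid <- cohort$template$grid
  } else grid <- NULL
  sidecar <- list(config = unclass(cohort$config),
                  truth = cohort$truth,
                  grid = if (!is.null(grid))
                    list(points = grid$points,
                         kernel_width = grid$kernel_width))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates that all per-subject files agree on the number of subjects and
#' that the status array is strictly binary.
#'
#' @param dir Cohort directory.
#' @return An `ssim_cohort` (template and truth restored when present).
#' @export
read_cohort <- function(dir) {
  moments <- read_matrix_txt(file.path(dir, "moments.csv"), "shape")
  dens <- read_matrix_txt(file.path(dir, "element_density.csv"),
                          "intensity")
  status <- read_matrix_txt(file.path(dir, "status.csv"), "status")
  abmd <- read_matrix_txt(file.path(dir, "abmd.csv"), "abmd")
  status <- as.vector(status)
  if (!all(status %in% c(0, 1)))
    stop(file.path(dir, "status.csv"),
         ": status must be binary 0/1; found value ",
         status[which(!status %in% c(0, 1))[1]], call. = FALSE)
  Ns <- c(nrow(moments), nrow(dens), length(status), nrow(abmd))
  if (length(unique(Ns)) != 1L)
    stop("inconsistent subject counts across cohort files: ",
         paste(Ns, collapse = "/"), call. = FALSE)
  cohort <- list(moments = .strip_kind(moments),
                 element_density = .strip_kind(dens),
                 status = as.integer(status),
                 abmd_analog = as.vector(abmd))
  side_path <- file.path(dir, "cohort.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    cohort$truth <- side$truth
    if (!is.null(side$config))
      cohort$config <- tryCatch(do.call(generator_config, side$config[
        setdiff(names(side$config), "n_fractured")]),
        error = function(e) side$config)
  }
  ply <- file.path(dir, "template_surface.ply")
  vtk <- file.path(dir, "template_volume.vtk")
  if (file.exists(ply) && file.exists(vtk)) {
    surf <- read_ply(ply)
    tet <- read_vtk_tet(vtk)
    grid <- NULL
    if (file.exists(side_path)) {
      side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
      if (!is.null(side$grid))
        grid <- control_grid(side$grid$points, side$grid$kernel_width)
    }
    cohort$template <- structure(list(surface = surf, tet = tet,
                                      grid = grid),
                                 class = "femur_template")
  }
  structure(cohort, class = "ssim_cohort")
}

.strip_kind <- function(x) { attr(x, "kind") <- NULL; x }
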