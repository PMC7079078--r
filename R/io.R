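# File I/O: the versioned JSON contour format, marker files, centerline
# CSV, and mesh export (binary little-endian PLY, legacy ASCII VTK).

CONTOUR_FORMAT <- "plaquediff-contours-v1"

#' Read a coronary tree from the JSON contour format
#'
#' The format is `{"format": "plaquediff-contours-v1", "ostium": [x,y,z],
#' "branches": [{"name", "contours": [{"center","normal","lumen","wall"}]}]}`
#' with all coordinates in mm. Contour winding is normalised to CCW about
#' the contour normal on read; all domain invariants are enforced.
#'
#' @param path path to a JSON contour file.
#' @return A validated [coronary_tree()].
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(doc$format, CONTOUR_FORMAT))
    stop("not a ", CONTOUR_FORMAT, " file: ", path)
  if (is.null(doc$branches) || length(doc$branches) == 0L)
    stop("contour file has no branches: ", path)
  branches <- lapply(seq_along(doc$branches$name), function(bi) {
    nm <- doc$branches$name[[bi]]
    cts <- doc$branches$contours[[bi]]
    lumen <- vector("list", length(cts$center))
    wall <- vector("list", length(cts$center))
    for (ci in seq_along(cts$center)) {
      lumen[[ci]] <- tryCatch(
        planar_contour(cts$center[[ci]], cts$normal[[ci]], cts$lumen[[ci]]),
        error = function(e) stop("branch '", nm, "' contour ", ci,
                                 " (lumen): ", conditionMessage(e)))
      wall[[ci]] <- tryCatch(
        planar_contour(cts$center[[ci]], cts$normal[[ci]], cts$wall[[ci]]),
        error = function(e) stop("branch '", nm, "' contour ", ci,
                                 " (wall): ", conditionMessage(e)))
    }
    vessel_branch(nm, lumen, wall)
  })
  coronary_tree(branches, doc$ostium)
}

#' Write a coronary tree to the JSON contour format
#'
#' Round-trips through [read_tree()] to within 1e-9 mm.
#'
#' @param tree a valid [coronary_tree()].
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  doc <- list(
    format = CONTOUR_FORMAT,
    ostium = tree$ostium,
    branches = lapply(unname(tree$branches), function(br) {
      list(name = br$name,
           contours = lapply(seq_along(br$lumen), function(i) {
             list(center = br$lumen[[i]]$center,
                  normal = br$lumen[[i]]$normal,
                  lumen = br$lumen[[i]]$points,
                  wall = br$wall[[i]]$points)
           }))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write marker files
#'
#' Markers are stored as a JSON list of `{"label", "bl": [x,y,z],
#' "fu": [x,y,z]}` records.
#'
#' @param path file path.
#' @return [read_markers()] returns a [marker_set()].
#' @export
read_markers <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  marker_set(doc$label,
             do.call(rbind, doc$bl),
             do.call(rbind, doc$fu))
}

#' @rdname read_markers
#' @param markers a [marker_set()].
#' @export
write_markers <- function(markers, path) {
  doc <- lapply(seq_len(nrow(markers)), function(i) {
    list(label = markers$label[i],
         bl = as.numeric(markers[i, c("bl.x", "bl.y", "bl.z")]),
         fu = as.numeric(markers[i, c("fu.x", "fu.y", "fu.z")]))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a centerline as CSV
#'
#' Columns: branch, s_mm (arclength from branch start), x, y, z.
#'
#' @param cl a [extract_centerline()] result.
#' @param path output path.
#' @export
write_centerline_csv <- function(cl, path) {
  utils::write.csv(
    data.frame(branch = cl$branch, s_mm = cl$arclengths,
               x = cl$points[, 1L], y = cl$points[, 2L], z = cl$points[, 3L]),
    path, row.names = FALSE)
  invisible(path)
}

# --- mesh export ------------------------------------------------------

#' Write a triangle mesh as binary little-endian PLY
#'
#' Optional per-vertex scalar (`double` property) and RGB colour
#' (`uchar` properties) are written alongside the coordinates.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param path output path.
#' @param scalar optional numeric length-n per-vertex scalar; stored as a
#'   double property named `quality`.
#' @param rgb optional n x 3 integer matrix of 0-255 vertex colours.
#' @export
write_ply <- function(vertices, faces, path, scalar = NULL, rgb = NULL) {
  n <- nrow(vertices); m <- nrow(faces)
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", n),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    hdr <- c(hdr, "property double quality")
  }
  if (!is.null(rgb)) {
    stopifnot(nrow(rgb) == n)
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  }
  hdr <- c(hdr, paste("element face", m),
           "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  for (i in seq_len(n)) {
    writeBin(as.numeric(vertices[i, ]), con, size = 8L, endian = "little")
    if (!is.null(scalar))
      writeBin(as.numeric(scalar[i]), con, size = 8L, endian = "little")
    if (!is.null(rgb))
      writeBin(as.raw(rgb[i, ]), con)
  }
  f0 <- faces - 1L
  for (i in seq_len(m)) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read back a PLY file written by [write_ply()]
#'
#' Minimal reader for this package's own binary PLY layout; used for
#' round-trip verification of exported scalar fields.
#'
#' @param path PLY file path.
#' @return list with `vertices`, `faces`, and (if present) `scalar`, `rgb`.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0L)
  repeat {
    ln <- readLines(con, n = 1L)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  n <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  m <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_scalar <- any(hdr == "property double quality")
  has_rgb <- any(hdr == "property uchar red")
  vertices <- matrix(0, n, 3L)
  scalar <- if (has_scalar) numeric(n) else NULL
  rgb <- if (has_rgb) matrix(0L, n, 3L) else NULL
  for (i in seq_len(n)) {
    vertices[i, ] <- readBin(con, "double", 3L, size = 8L, endian = "little")
    if (has_scalar)
      scalar[i] <- readBin(con, "double", 1L, size = 8L, endian = "little")
    if (has_rgb)
      rgb[i, ] <- as.integer(readBin(con, "raw", 3L))
  }
  faces <- matrix(0L, m, 3L)
  for (i in seq_len(m)) {
    readBin(con, "raw", 1L)
    faces[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little") + 1L
  }
  list(vertices = vertices, faces = faces, scalar = scalar, rgb = rgb)
}

#' Write a triangle mesh as legacy ASCII VTK polydata
#'
#' @inheritParams write_ply
#' @param scalar_name name of the point-data scalar array.
#' @param rgb optional n x 3 integer matrix written as `Colors` uchar array.
#' @export
write_vtk <- function(vertices, faces, path, scalar = NULL,
                      scalar_name = "scalar", rgb = NULL) {
  n <- nrow(vertices); m <- nrow(faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "plaquediff surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "double")), con)
  utils::write.table(format(vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(paste("POLYGONS", m, 4L * m), con)
  utils::write.table(cbind(3L, faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(scalar) || !is.null(rgb))
    writeLines(paste("POINT_DATA", n), con)
  if (!is.null(scalar)) {
    writeLines(c(paste("SCALARS", scalar_name, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(scalar, digits = 17, trim = TRUE, scientific = FALSE),
               con)
  }
  if (!is.null(rgb)) {
    writeLines(paste("COLOR_SCALARS Colors 3"), con)
    utils::write.table(format(rgb / 255, digits = 6, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
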