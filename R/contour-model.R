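#' Planar cross-sectional contour
#'
#' A closed cross-sectional polygon (lumen or vessel-wall boundary) living
#' in a plane in 3D patient coordinates. Points are stored open (the last
#' vertex connects implicitly back to the first), ordered counter-clockwise
#' about the plane normal. Orientation is normalised on construction.
#'
#' @param center numeric length-3 plane reference point (mm), expected to
#'   lie inside the polygon.
#' @param normal numeric length-3 plane normal (normalised internally).
#' @param points numeric n x 3 matrix of polygon vertices (mm), n >= 8.
#' @param validate logical; run invariant checks (default `TRUE`).
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(center, normal, points, validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  ct <- structure(
    list(center = as.numeric(center), normal = unit(as.numeric(normal)),
         points = points),
    class = "planar_contour")
  # normalise winding to CCW about the normal
  b <- plane_basis(ct$normal)
  xy <- to_plane_2d(ct$points, ct$center, b)
  if (polygon_area_2d(xy) < 0)
    ct$points <- ct$points[rev(seq_len(nrow(ct$points))), , drop = FALSE]
  if (validate) validate_contour(ct)
  ct
}

#' @rdname planar_contour
#' @param contour a `planar_contour`.
#' @export
validate_contour <- function(contour) {
  pts <- contour$points
  if (nrow(pts) < 8L)
    stop("contour must have at least 8 points, got ", nrow(pts))
  if (length(contour$center) != 3L || length(contour$normal) != 3L)
    stop("center and normal must be length-3")
  # coplanarity with (center, normal)
  d <- sweep(pts, 2L, contour$center) %*% contour$normal
  if (max(abs(d)) > 1e-6)
    stop(sprintf("contour points deviate from plane by %.3g mm (> 1e-6)",
                 max(abs(d))))
  b <- plane_basis(contour$normal)
  xy <- to_plane_2d(pts, contour$center, b)
  if (polygon_area_2d(xy) <= 0)
    stop("contour polygon is degenerate or not CCW about its normal")
  if (!polygon_is_simple(xy))
    stop("contour polygon is self-intersecting")
  if (!point_in_polygon_2d(matrix(0, 1L, 2L), xy))
    stop("contour center lies outside the polygon")
  invisible(contour)
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2) on the
# small per-contour point counts used here.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # edge n is adjacent to edge 1
    if (i == 1L) js <- js[js != n]
    p <- a[i, ]; r <- b[i, ] - p
    q1 <- a[js, , drop = FALSE]; q2 <- b[js, , drop = FALSE]
    s1 <- sweep(q1, 2L, p); s2 <- sweep(q2, 2L, p)
    c1 <- r[1L] * s1[, 2L] - r[2L] * s1[, 1L]
    c2 <- r[1L] * s2[, 2L] - r[2L] * s2[, 1L]
    straddle1 <- (c1 > 1e-12 & c2 < -1e-12) | (c1 < -1e-12 & c2 > 1e-12)
    if (!any(straddle1)) next
    for (k in which(straddle1)) {
      j <- js[k]
      pq <- a[j, ]; rq <- b[j, ] - pq
      d1 <- rq[1L] * (p[2L] - pq[2L]) - rq[2L] * (p[1L] - pq[1L])
      d2 <- rq[1L] * (p[2L] + r[2L] - pq[2L]) - rq[2L] * (p[1L] + r[1L] - pq[1L])
      if ((d1 > 1e-12 && d2 < -1e-12) || (d1 < -1e-12 && d2 > 1e-12))
        return(FALSE)
    }
  }
  TRUE
}

# Points-in-polygon with "on the boundary counts as inside" semantics.
point_in_polygon_2d <- function(pts, poly, tol = 1e-9) {
  inside <- mgcv::in.out(rbind(poly, poly[1L, ]), pts)
  on_bd <- dist_to_polygon_2d(pts, poly) <= tol
  inside | on_bd
}

#' Test whether one coplanar contour contains another
#'
#' Returns `TRUE` iff every vertex of `inner` lies inside or on the
#' boundary of `outer`, evaluated as 2D point-in-polygon in the shared
#' contour plane. Coincident polygons therefore contain each other, which
#' is the zero-thickness convention for vessel-wall contours drawn on top
#' of the lumen where no plaque is present.
#'
#' @param outer,inner `planar_contour` objects sharing a plane.
#' @param tol boundary tolerance in mm.
#' @return logical scalar.
#' @export
polygon_contains <- function(outer, inner, tol = 1e-6) {
  if (max(abs(sweep(inner$points, 2L, outer$center) %*% outer$normal)) > 1e-4)
    stop("contours are not coplanar")
  b <- plane_basis(outer$normal)
  opoly <- to_plane_2d(outer$points, outer$center, b)
  ipts <- to_plane_2d(inner$points, outer$center, b)
  all(point_in_polygon_2d(ipts, opoly, tol = tol))
}

#' Vessel branch: an ordered stack of paired lumen/wall contours
#'
#' @param name branch label, e.g. `"RCA"`, `"LAD"`, `"LCx"`.
#' @param lumen,wall lists of [planar_contour()] of equal length, ordered
#'   proximal to distal. Each pair shares its center and normal; the wall
#'   contour contains (or coincides with) the lumen contour.
#' @param validate logical; run invariant checks.
#' @return An object of class `vessel_branch`.
#' @export
vessel_branch <- function(name, lumen, wall, validate = TRUE) {
  br <- structure(list(name = as.character(name), lumen = lumen, wall = wall),
                  class = "vessel_branch")
  if (validate) validate_branch(br)
  br
}

#' @rdname vessel_branch
#' @param branch a `vessel_branch`.
#' @export
validate_branch <- function(branch) {
  nl <- length(branch$lumen); nw <- length(branch$wall)
  if (nl != nw) stop("branch '", branch$name, "': ", nl, " lumen vs ",
                     nw, " wall contours")
  if (nl < 1L) stop("branch '", branch$name, "' has no contours")
  for (i in seq_len(nl)) {
    lu <- branch$lumen[[i]]; wa <- branch$wall[[i]]
    if (vec_norm(lu$center - wa$center) > 1e-6 ||
        vec_norm(lu$normal - wa$normal) > 1e-6)
      stop("branch '", branch$name, "' contour ", i,
           ": lumen and wall do not share center/normal")
    if (!polygon_contains(wa, lu, tol = 1e-6))
      stop("branch '", branch$name, "' contour ", i,
           ": wall polygon does not contain the lumen polygon")
  }
  centers <- t(vapply(branch$lumen, `[[`, numeric(3L), "center"))
  if (nl > 1L) {
    steps <- row_norms(diff(centers))
    if (any(steps < 1e-9))
      stop("branch '", branch$name, "': consecutive contour centers coincide")
  }
  invisible(branch)
}

#' Coronary artery tree
#'
#' @param branches list of [vessel_branch()] objects with unique names.
#' @param ostium numeric length-3 coronary ostium location (mm), the
#'   arclength reference point.
#' @param validate logical; run invariant checks.
#' @return An object of class `coronary_tree`.
#' @export
coronary_tree <- function(branches, ostium, validate = TRUE) {
  names(branches) <- vapply(branches, `[[`, character(1L), "name")
  tr <- structure(list(branches = branches, ostium = as.numeric(ostium)),
                  class = "coronary_tree")
  if (validate) validate_tree(tr)
  tr
}

#' @rdname coronary_tree
#' @param tree a `coronary_tree`.
#' @export
validate_tree <- function(tree) {
  if (length(tree$branches) < 1L) stop("tree must have at least one branch")
  nm <- vapply(tree$branches, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("branch names are not unique: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  if (length(tree$ostium) != 3L) stop("ostium must be a 3D point")
  for (br in tree$branches) validate_branch(br)
  invisible(tree)
}

#' @export
print.coronary_tree <- function(x, ...) {
  cat("coronary_tree:", length(x$branches), "branch(es)\n")
  for (br in x$branches)
    cat(sprintf("  %-4s %3d contour pairs\n", br$name, length(br$lumen)))
  invisible(x)
}

#' Marker pairs for registration evaluation
#'
#' Anatomically labelled corresponding points on the baseline and follow-up
#' centerlines (start/proximal/middle/distal/end per branch).
#'
#' @param label character vector of tags such as `"mRCA"`; the leading
#'   letter must be one of s, p, m, d, e.
#' @param bl,fu n x 3 matrices of marker coordinates (mm) in baseline and
#'   follow-up space.
#' @return A data.frame of class `marker_set` with columns label,
#'   bl.x/y/z, fu.x/y/z.
#' @export
marker_set <- function(label, bl, fu) {
  bl <- matrix(as.numeric(bl), ncol = 3L)
  fu <- matrix(as.numeric(fu), ncol = 3L)
  stopifnot(length(label) == nrow(bl), nrow(bl) == nrow(fu))
  bad <- !substr(label, 1L, 1L) %in% c("s", "p", "m", "d", "e")
  if (any(bad))
    stop("marker labels must start with one of s/p/m/d/e: ",
         paste(label[bad], collapse = ", "))
  structure(data.frame(label = label,
                       bl.x = bl[, 1L], bl.y = bl[, 2L], bl.z = bl[, 3L],
                       fu.x = fu[, 1L], fu.y = fu[, 2L], fu.z = fu[, 3L],
                       stringsAsFactors = FALSE),
            class = c("marker_set", "data.frame"))
}
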