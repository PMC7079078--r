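# Low-level vector/plane/polygon geometry shared across the package.
# All coordinates are millimetres in patient space.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Rotation matrix from an axis and angle
#'
#' Rodrigues' formula; `axis` need not be normalised.
#'
#' @param axis numeric length-3 rotation axis.
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rotation_axis_angle <- function(axis, angle) {
  u <- unit(axis)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Orthonormal in-plane basis (e1, e2) for a plane with unit normal n,
# with e1 x e2 = n so that CCW in (e1,e2) is CCW about n.
plane_basis <- function(normal) {
  n <- unit(normal)
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(cross3(ref, n))
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2, n = n)
}

# Project rows of 3D points into a plane's 2D coordinates.
to_plane_2d <- function(points, center, basis) {
  d <- sweep(points, 2L, center)
  cbind(d %*% basis$e1, d %*% basis$e2)
}

# Signed area of a 2D polygon (positive = counter-clockwise).
polygon_area_2d <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Area centroid of a simple 2D polygon (shoelace centroid).
polygon_centroid_2d <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) stop("degenerate polygon: area is (near) zero")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Minimum distance from 2D points to a closed polygon boundary.
dist_to_polygon_2d <- function(pts, poly) {
  a <- poly
  b <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE]
  dmin <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(a))) {
    e <- b[s, ] - a[s, ]
    l2 <- sum(e * e)
    w1 <- pts[, 1L] - a[s, 1L]; w2 <- pts[, 2L] - a[s, 2L]
    t <- if (l2 < 1e-18) rep(0, nrow(pts)) else
      pmin(1, pmax(0, (w1 * e[1L] + w2 * e[2L]) / l2))
    dx <- w1 - t * e[1L]; dy <- w2 - t * e[2L]
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

# Rotation-minimizing frames along a polyline (double-reflection method).
# Returns list of e1/e2 matrices (n x 3): an orthonormal frame per point
# with minimal twist, e1 x e2 = tangent.
rmf_frames <- function(points) {
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points for frames")
  tang <- matrix(0, n, 3L)
  tang[1L, ] <- unit(points[2L, ] - points[1L, ])
  if (n > 2L) for (i in 2L:(n - 1L))
    tang[i, ] <- unit(points[i + 1L, ] - points[i - 1L, ])
  tang[n, ] <- unit(points[n, ] - points[n - 1L, ])
  e1 <- matrix(0, n, 3L); e2 <- matrix(0, n, 3L)
  b <- plane_basis(tang[1L, ])
  e1[1L, ] <- b$e1; e2[1L, ] <- b$e2
  for (i in seq_len(n - 1L)) {
    # reflect across bisecting plane of the segment, then across the
    # bisecting plane of the reflected and next tangents
    v1 <- points[i + 1L, ] - points[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
    v2 <- tang[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    e1n <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    e1n <- unit(e1n - sum(e1n * tang[i + 1L, ]) * tang[i + 1L, ])
    e1[i + 1L, ] <- e1n
    e2[i + 1L, ] <- cross3(tang[i + 1L, ], e1n)
  }
  list(e1 = e1, e2 = e2, tangent = tang)
}
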