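# Branch centerlines: area centroids of the lumen contours, cubic-spline
# resampled to a uniform 0.5 mm arclength spacing.

#' Extract a branch centerline from its lumen contours
#'
#' One centerline point per contour: the area centroid of the lumen
#' polygon evaluated in its own plane. For tubular cross-sections this is
#' the medial point of the lumen; arclengths are cumulative chord lengths
#' from the proximal end, and `distance_to_ostium` offsets the branch into
#' a tree-global parameter.
#'
#' @param branch a [vessel_branch()] with at least 2 contour pairs.
#' @param ostium optional length-3 ostium point used for the offset.
#' @return An object of class `centerline` with fields `branch`, `points`
#'   (n x 3 mm), `arclengths` (mm) and `distance_to_ostium` (mm).
#' @export
extract_centerline <- function(branch, ostium = NULL) {
  n <- length(branch$lumen)
  if (n < 2L) stop("branch '", branch$name, "' has fewer than 2 contours")
  pts <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    ct <- branch$lumen[[i]]
    b <- plane_basis(ct$normal)
    xy <- to_plane_2d(ct$points, ct$center, b)
    c2 <- polygon_centroid_2d(xy)
    pts[i, ] <- ct$center + c2[1L] * b$e1 + c2[2L] * b$e2
  }
  arc <- c(0, cumsum(row_norms(diff(pts))))
  d0 <- if (is.null(ostium)) 0 else vec_norm(pts[1L, ] - ostium)
  structure(list(branch = branch$name, points = pts, arclengths = arc,
                 distance_to_ostium = d0),
            class = "centerline")
}

#' Resample a centerline at uniform arclength spacing
#'
#' Fits a natural cubic spline through the centerline points per
#' coordinate, parameterized by cumulative chord length, and samples every
#' `spacing` mm from the proximal end. Both endpoints are preserved; the
#' final interval may be shorter than `spacing`.
#'
#' @param cl a [extract_centerline()] result with >= 4 points.
#' @param spacing target spacing in mm (default 0.5).
#' @return A resampled `centerline`.
#' @export
resample_centerline <- function(cl, spacing = 0.5) {
  n <- nrow(cl$points)
  if (n < 4L) stop("need at least 4 centerline points for cubic spline")
  total <- cl$arclengths[n]
  s_out <- seq(0, total, by = spacing)
  if (total - s_out[length(s_out)] > 1e-9) s_out <- c(s_out, total)
  pts <- vapply(1:3, function(j)
    stats::spline(cl$arclengths, cl$points[, j], xout = s_out,
                  method = "natural")$y,
    numeric(length(s_out)))
  structure(list(branch = cl$branch, points = pts, arclengths = s_out,
                 distance_to_ostium = cl$distance_to_ostium,
                 spacing = spacing),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline '%s': %d points, %.1f mm\n", x$branch,
              nrow(x$points), x$arclengths[length(x$arclengths)]))
  invisible(x)
}
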