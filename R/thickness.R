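# Per-vertex plaque thickness, baseline/follow-up differencing, threshold
# classification, regional statistics and colored-mesh export.

#' Per-vertex plaque thickness between a lumen and a wall surface
#'
#' Thickness at a lumen vertex is the Euclidean distance to the wall
#' vertex carrying the same ancestry id (the correspondence established by
#' the shared coarse mesh).
#'
#' @param lumen,wall fitted [fit_to_contours()] surfaces refined from the
#'   same coarse mesh.
#' @return An object of class `thickness_field`: data.frame with columns
#'   `ancestry`, `branch`, `station` (mm), `is_cap`, `thickness` (mm).
#' @export
compute_thickness <- function(lumen, wall) {
  if (!identical(lumen$ancestry, wall$ancestry)) {
    if (!setequal(lumen$ancestry, wall$ancestry))
      stop("lumen and wall surfaces have different ancestry id sets")
    wall_idx <- match(lumen$ancestry, wall$ancestry)
  } else wall_idx <- seq_along(lumen$ancestry)
  th <- row_norms(lumen$vertices - wall$vertices[wall_idx, , drop = FALSE])
  station <- if (!is.null(lumen$station)) lumen$station else
    stats::approx(seq_along(lumen$stations), lumen$stations,
                  xout = pmin(pmax(lumen$ring_coord, 1),
                              length(lumen$stations)))$y
  structure(data.frame(ancestry = lumen$ancestry, branch = lumen$branch,
                       station = station, is_cap = lumen$is_cap,
                       thickness = th, stringsAsFactors = FALSE),
            class = c("thickness_field", "data.frame"))
}

#' Per-vertex plaque thickness difference over time
#'
#' Signed change per ancestry id with positive values meaning plaque
#' progression (the follow-up is thicker than the baseline); exactly
#' antisymmetric under swapping the two fields. Stations and branch labels
#' are taken from the baseline field.
#'
#' @param bl,fu baseline and follow-up [compute_thickness()] fields with
#'   identical ancestry id sets.
#' @return An object of class `diff_field`: data.frame with `ancestry`,
#'   `branch`, `station`, `is_cap`, `diff` (mm).
#' @export
compute_diff <- function(bl, fu) {
  idx <- if (identical(fu$ancestry, bl$ancestry)) seq_len(nrow(bl)) else
    match(bl$ancestry, fu$ancestry)
  if (anyNA(idx))
    stop("baseline and follow-up thickness fields have different ancestry sets")
  structure(data.frame(ancestry = bl$ancestry, branch = bl$branch,
                       station = bl$station, is_cap = bl$is_cap,
                       diff = fu$thickness[idx] - bl$thickness,
                       stringsAsFactors = FALSE),
            class = c("diff_field", "data.frame"))
}

#' Classify per-vertex thickness changes against a threshold
#'
#' Differences above `threshold` are `increase`, below `-threshold` are
#' `decrease`, and the closed interval `[-threshold, threshold]` is
#' `no_change` (boundary values count as no change).
#'
#' @param diff a [compute_diff()] field.
#' @param threshold classification cut-off in mm (default 0.5).
#' @return The field with an added factor column `class`.
#' @export
classify_changes <- function(diff, threshold = 0.5) {
  stopifnot(threshold > 0)
  cls <- rep("no_change", nrow(diff))
  cls[diff$diff > threshold] <- "increase"
  cls[diff$diff < -threshold] <- "decrease"
  diff$class <- factor(cls, levels = c("decrease", "no_change", "increase"))
  attr(diff, "threshold") <- threshold
  diff
}

#' Regional statistics of a difference field
#'
#' Unweighted per-vertex statistics over the vertices of `branch` whose
#' axial station falls in `window`; cap vertices are excluded.
#'
#' @param diff a [compute_diff()] (optionally classified) field.
#' @param branch branch name, or `NULL` for all branches.
#' @param window length-2 arclength window (mm), or `NULL` for the whole
#'   branch.
#' @return list with `mean`, `sd`, `min`, `max` (mm), `n`, and (when the
#'   field is classified) `pct_increase`, `pct_decrease`.
#' @export
region_stats <- function(diff, branch = NULL, window = NULL) {
  sel <- !diff$is_cap
  if (!is.null(branch)) sel <- sel & diff$branch == branch
  if (!is.null(window))
    sel <- sel & diff$station >= window[1L] & diff$station <= window[2L]
  if (!any(sel)) stop("empty region")
  x <- diff$diff[sel]
  out <- list(mean = mean(x), sd = stats::sd(x), min = min(x),
              max = max(x), n = sum(sel))
  if (!is.null(diff$class)) {
    out$pct_increase <- 100 * mean(diff$class[sel] == "increase")
    out$pct_decrease <- 100 * mean(diff$class[sel] == "decrease")
  }
  out
}

#' Export a surface with a per-vertex field as a colored mesh
#'
#' Writes PLY (binary little-endian) or legacy VTK polydata with the field
#' as a per-vertex scalar plus RGB colours. In `"thresholded"` mode,
#' vertices classified as increase are red, decrease yellow and no-change
#' neutral gray; in `"continuous"` mode a blue-gray-red diverging ramp is
#' applied over the symmetric data range.
#'
#' @param surface the `subdiv_surface` the field lives on.
#' @param field a `thickness_field` or `diff_field` matching the surface.
#' @param path output path; extension selects the writer (`.ply`/`.vtk`).
#' @param mode `"continuous"` or `"thresholded"`.
#' @param threshold cut-off for thresholded mode (mm).
#' @export
export_colored <- function(surface, field, path,
                           mode = c("continuous", "thresholded"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  vals <- if (!is.null(field$diff)) field$diff else field$thickness
  if (length(vals) != nrow(surface$vertices))
    stop("field length does not match surface vertex count")
  if (mode == "thresholded") {
    cls <- if (!is.null(field$class)) as.character(field$class) else {
      cf <- classify_changes(field, threshold)
      as.character(cf$class)
    }
    rgb <- matrix(190L, length(vals), 3L)         # neutral gray
    rgb[cls == "increase", ] <- rep(c(220L, 30L, 30L), each = sum(cls == "increase"))
    rgb[cls == "decrease", ] <- rep(c(235L, 200L, 30L), each = sum(cls == "decrease"))
  } else {
    r <- max(abs(vals), 1e-9)
    u <- (vals / r + 1) / 2  # 0..1, 0.5 = zero change
    ramp <- grDevices::colorRamp(c("#2166AC", "#BEBEBE", "#B2182B"))(u)
    rgb <- matrix(as.integer(round(ramp)), ncol = 3L)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "vtk")
    write_vtk(surface$vertices, surface$faces, path, scalar = vals,
              scalar_name = if (!is.null(field$diff)) "DIF_thickness"
              else "thickness", rgb = rgb)
  else
    write_ply(surface$vertices, surface$faces, path, scalar = vals,
              rgb = rgb)
  invisible(path)
}

#' Plot thickness along an artery
#'
#' Baseline thickness, follow-up thickness and their difference against
#' arclength for one branch, summarised per station bin.
#'
#' @param bl,fu [compute_thickness()] fields.
#' @param diff a [compute_diff()] field.
#' @param branch branch name.
#' @param bin station bin width (mm).
#' @export
plot_thickness_profile <- function(bl, fu, diff, branch, bin = 0.5) {
  sel <- bl$branch == branch & !bl$is_cap
  s <- bl$station[sel]
  br <- function(v) tapply(v, round(s / bin) * bin, mean)
  sb <- as.numeric(names(br(s)))
  graphics::plot(sb, br(bl$thickness[sel]), type = "l", col = "blue",
                 xlab = "arclength (mm)", ylab = "thickness (mm)",
                 main = paste("plaque thickness:", branch),
                 ylim = range(c(br(bl$thickness[sel]), br(fu$thickness[sel]),
                                br(diff$diff[sel]))))
  graphics::lines(sb, br(fu$thickness[sel]), col = "darkgreen")
  graphics::lines(sb, br(diff$diff[sel]), col = "red")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", c("BL", "FU", "difference"), lty = 1,
                   col = c("blue", "darkgreen", "red"), bty = "n")
  invisible(NULL)
}
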