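# Subdivision-surface fitting: an initial tube grows toward target
# contours, each vertex pushed along its normal by a force equal to its
# signed distance to the axially interpolated target contour, plus
# umbrella-Laplacian regularisation.

#' Build a fitting target from a branch's contours
#'
#' Represents one side (lumen or wall) of a branch as an angularly
#' resampled stack: every contour is sampled at `K` fixed azimuths in
#' rotation-minimizing frames propagated along the contour centers, giving
#' a radius table that can be interpolated axially (between contours) as
#' well as used for ray casting. Vessel cross-sections are assumed
#' star-shaped about the contour center.
#'
#' @param branch a [vessel_branch()].
#' @param side `"lumen"` or `"wall"`.
#' @param K angular samples per contour.
#' @return An object of class `contour_stack`: `s` (arclength per contour,
#'   mm), `centers`, frame vectors `e1`/`e2`/`nrm`, `radii` (n x K),
#'   `theta`.
#' @export
contour_stack <- function(branch, side = c("lumen", "wall"), K = 48L) {
  side <- match.arg(side)
  cts <- branch[[side]]
  n <- length(cts)
  centers <- t(vapply(cts, `[[`, numeric(3L), "center"))
  s <- c(0, cumsum(row_norms(diff(centers))))
  frames <- rmf_frames(centers)
  theta <- (seq_len(K) - 1L) * 2 * pi / K
  radii <- matrix(0, n, K)
  e1m <- matrix(0, n, 3L); e2m <- matrix(0, n, 3L); nm <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    ct <- cts[[i]]
    nrm <- ct$normal
    if (sum(nrm * frames$tangent[i, ]) < 0) nrm <- -nrm
    e1 <- frames$e1[i, ] - sum(frames$e1[i, ] * nrm) * nrm
    e1 <- unit(e1)
    e2 <- cross3(nrm, e1)
    b <- list(e1 = e1, e2 = e2, n = nrm)
    xy <- to_plane_2d(ct$points, ct$center, b)
    radii[i, ] <- .star_radii(xy, theta)
    e1m[i, ] <- e1; e2m[i, ] <- e2; nm[i, ] <- nrm
  }
  structure(list(s = s, centers = centers, e1 = e1m, e2 = e2m, nrm = nm,
                 radii = radii, theta = theta, branch = branch$name,
                 side = side),
            class = "contour_stack")
}

# Radius of a closed 2D polygon along rays from the origin at the given
# angles. The polygon must be star-shaped about the origin (vertex
# azimuths strictly advancing CCW); the bracketing edge is found by
# angle, then intersected exactly, which is robust when a ray passes
# through a vertex.
.star_radii <- function(xy, theta) {
  Kp <- nrow(xy)
  phi <- atan2(xy[, 2L], xy[, 1L])
  dphi <- diff(phi) %% (2 * pi)
  if (any(dphi <= 0 | dphi >= pi) ||
      ((phi[1L] - phi[Kp]) %% (2 * pi)) >= pi)
    stop("contour is not star-shaped about its center")
  up <- phi[1L] + cumsum(c(0, dphi))
  th <- up[1L] + ((theta - up[1L]) %% (2 * pi))
  i <- findInterval(th, up)
  i2 <- i %% Kp + 1L
  ax <- xy[i, 1L]; ay <- xy[i, 2L]
  ex <- xy[i2, 1L] - ax; ey <- xy[i2, 2L] - ay
  dx <- cos(theta); dy <- sin(theta)
  (ax * ey - ay * ex) / (dx * ey - dy * ex)
}

# Per-vertex axial interpolation of a contour stack at the surface's
# fractional ring coordinates. Returns plane origin, orthonormal basis and
# the 2D target polygon (radius per azimuth) per vertex.
.vertex_targets <- function(surface, stack) {
  s_v <- stats::approx(seq_along(surface$stations), surface$stations,
                       xout = pmin(pmax(surface$ring_coord, 1),
                                   length(surface$stations)))$y
  s_v <- pmin(pmax(s_v, stack$s[1L]), stack$s[length(stack$s)])
  idx <- findInterval(s_v, stack$s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(stack$s) - 1L)
  al <- (s_v - stack$s[idx]) / (stack$s[idx + 1L] - stack$s[idx])
  al <- pmin(pmax(al, 0), 1)
  o <- (1 - al) * stack$centers[idx, , drop = FALSE] +
    al * stack$centers[idx + 1L, , drop = FALSE]
  nrm <- (1 - al) * stack$nrm[idx, , drop = FALSE] +
    al * stack$nrm[idx + 1L, , drop = FALSE]
  nrm <- nrm / row_norms(nrm)
  e1 <- (1 - al) * stack$e1[idx, , drop = FALSE] +
    al * stack$e1[idx + 1L, , drop = FALSE]
  e1 <- e1 - rowSums(e1 * nrm) * nrm
  e1 <- e1 / row_norms(e1)
  e2 <- cross3_rows(nrm, e1)
  radii <- (1 - al) * stack$radii[idx, , drop = FALSE] +
    al * stack$radii[idx + 1L, , drop = FALSE]
  list(origin = o, e1 = e1, e2 = e2, nrm = nrm, radii = radii,
       theta = stack$theta, station = s_v)
}

# Signed distance from each vertex to its 2D target polygon along the
# in-plane projection of its normal (the contour is planar, so the
# distance -- and the resulting motion -- live in the contour plane;
# this prevents end-ring vertices with axially tilted normals from
# sliding along the vessel). Zero where the normal is (nearly)
# perpendicular to the contour plane (cap regions). Returns the force
# vector with the unit in-plane direction as attribute "dir".
.normal_forces <- function(V, normals, tg) {
  nv <- nrow(V)
  d <- V - tg$origin
  px <- rowSums(d * tg$e1); py <- rowSums(d * tg$e2)
  qx <- rowSums(normals * tg$e1); qy <- rowSums(normals * tg$e2)
  qn <- sqrt(qx * qx + qy * qy)
  ok <- qn > 0.2
  qx <- qx / pmax(qn, 1e-12); qy <- qy / pmax(qn, 1e-12)
  K <- length(tg$theta)
  ct <- cos(tg$theta); st <- sin(tg$theta)
  # polygon vertices per surface vertex: a_j = r_j * (cos, sin)
  tbest <- rep(Inf, nv)
  for (j in seq_len(K)) {
    j2 <- if (j == K) 1L else j + 1L
    ax <- tg$radii[, j] * ct[j] - px
    ay <- tg$radii[, j] * st[j] - py
    ex <- tg$radii[, j2] * ct[j2] - px - ax
    ey <- tg$radii[, j2] * st[j2] - py - ay
    den <- qx * ey - qy * ex
    t <- (ax * ey - ay * ex) / den
    u <- (ax * qy - ay * qx) / den
    valid <- abs(den) > 1e-14 & u >= -1e-6 & u <= 1 + 1e-6
    t[!valid] <- Inf
    take <- abs(t) < abs(tbest)
    tbest[take] <- t[take]
  }
  tbest[!ok | !is.finite(tbest)] <- 0
  attr(tbest, "dir") <- qx * tg$e1 + qy * tg$e2
  tbest
}

#' Fit a subdivision surface to target contours
#'
#' Iteratively moves every vertex along its (area-weighted) normal by
#' `step` times its signed distance to the axially interpolated target
#' contour, plus `smooth_weight` times the umbrella Laplacian. Stops when
#' the largest force magnitude drops below `force_tol` or after
#' `max_iter` iterations. Ancestry ids are untouched, so correspondence
#' established by the coarse mesh survives fitting.
#'
#' @param surface a [subdivide()] result spanning the target's axial range.
#' @param stack a [contour_stack()] of target contours.
#' @param max_iter maximum iterations.
#' @param step force step factor.
#' @param smooth_weight umbrella-Laplacian weight.
#' @param smooth_normal fraction of the Laplacian's surface-normal
#'   component retained. The umbrella operator on a discretised tube has
#'   an inward radial bias of order `r (1 - cos(2 pi / n))` that would
#'   otherwise balance the fitting force at a standing residual;
#'   attenuating the normal component removes most of that shrinkage bias
#'   while keeping full tangential regularisation.
#' @param force_tol convergence threshold on the max force (mm).
#' @return The fitted `subdiv_surface`; component `fit` holds
#'   `iterations`, `rms` (final RMS vertex-to-contour distance, mm),
#'   `max_force`, `converged`.
#' @export
fit_to_contours <- function(surface, stack, max_iter = 80L, step = 0.5,
                            smooth_weight = 0.2, smooth_normal = 0.25,
                            force_tol = 0.02) {
  V <- surface$vertices
  F <- surface$faces
  tg <- .vertex_targets(surface, stack)
  free <- !surface$is_cap
  # tube vertices are smoothed over tube neighbours only; cap vertices
  # carry no fitting force and simply relax to their neighbourhood
  # average, so the end caps follow their rings without dragging them
  # toward the centerline
  A <- adjacency_operator(nrow(V), F, drop_to = free)
  A_cap <- if (any(!free))
    adjacency_operator(nrow(V), F)[!free, , drop = FALSE] else NULL
  # normals for the fitting force come from tube faces only: the large
  # cap triangles would otherwise tilt end-ring normals axially and
  # disable their force
  F_tube <- F[free[F[, 1L]] & free[F[, 2L]] & free[F[, 3L]], , drop = FALSE]
  rms_prev <- Inf; n_grow <- 0L
  converged <- FALSE
  f <- numeric(nrow(V))
  for (it in seq_len(max_iter)) {
    nrm <- vertex_normals(V, F_tube)
    f <- .normal_forces(V, nrm, tg)
    f[surface$is_cap] <- 0
    fdir <- attr(f, "dir")
    lap <- as.matrix(A %*% V) - V
    lap <- lap - (1 - smooth_normal) * rowSums(lap * nrm) * nrm
    V[free, ] <- V[free, ] + step * as.numeric(f)[free] *
      fdir[free, , drop = FALSE] + smooth_weight * lap[free, , drop = FALSE]
    if (!is.null(A_cap)) V[!free, ] <- as.matrix(A_cap %*% V)
    rms <- sqrt(mean(f[free]^2))
    # genuine divergence: sustained substantial growth, not terminal
    # oscillation around the smoothing/force equilibrium
    if (rms > 1.05 * rms_prev && rms > 0.25)
      n_grow <- n_grow + 1L else n_grow <- 0L
    if (n_grow >= 10L)
      stop(sprintf(
        "subdivision fit diverging on branch '%s' (%s): RMS force grew for 10 iterations (now %.3f mm)",
        surface$branch, stack$side, rms))
    rms_prev <- rms
    if (max(abs(f[free])) < force_tol) {
      converged <- TRUE
      break
    }
  }
  nrm <- vertex_normals(V, F_tube)
  f_final <- .normal_forces(V, nrm, tg)
  f_final[surface$is_cap] <- 0
  surface$vertices <- V
  surface$station <- tg$station
  surface$fit <- list(iterations = it,
                      rms = sqrt(mean(f_final[free]^2)),
                      max_force = max(abs(f_final[free])),
                      converged = converged)
  surface
}

#' Fit lumen and wall surfaces from one coarse mesh
#'
#' The lumen surface is fitted starting from the subdivided coarse tube;
#' the fitted lumen surface then initialises the vessel-wall fit, which
#' grows outward to the wall contours. Both surfaces carry the identical
#' ancestry id set, which defines the lumen-to-wall point correspondence
#' used for thickness measurement.
#'
#' @param coarse a [build_coarse_mesh()] result.
#' @param lumen_stack,wall_stack [contour_stack()] targets.
#' @param levels subdivision depth.
#' @param ... fitting controls passed to [fit_to_contours()].
#' @return list with `lumen` and `wall` fitted surfaces.
#' @export
fit_lumen_then_wall <- function(coarse, lumen_stack, wall_stack,
                                levels = 2L, ...) {
  init <- subdivide(coarse, levels)
  lumen <- fit_to_contours(init, lumen_stack, ...)
  wall <- fit_to_contours(lumen, wall_stack, ...)
  list(lumen = lumen, wall = wall)
}

#' Map a follow-up coarse mesh into baseline coordinates
#'
#' Every hexagonal ring is first moved by the global rigid transform and
#' then translated by the residual translation vector of its centerline
#' point from the one-to-one correspondence; rings whose centerline point
#' is unmatched get a translation interpolated linearly (per component)
#' along the ring index from the nearest matched rings. Ring-for-ring and
#' vertex-for-vertex correspondence with the input is preserved.
#'
#' @param fu_coarse the follow-up [build_coarse_mesh()] result.
#' @param cmap a [resolve_correspondence()] result.
#' @param transform the follow-up-to-baseline [rigid_transform()].
#' @param index_offset offset of this branch's first ring in the pooled
#'   follow-up point indexing used by `cmap`.
#' @return A `hex_ring_mesh` in baseline coordinates.
#' @export
map_coarse_mesh <- function(fu_coarse, cmap, transform, index_offset = 0L) {
  n <- dim(fu_coarse$rings)[1L]
  ring_fu_idx <- index_offset + seq_len(n)
  m <- match(ring_fu_idx, cmap$pairs$fu)
  matched <- which(!is.na(m))
  if (length(matched) == 0L)
    stop("no matched rings for branch '", fu_coarse$branch, "'")
  Tv <- matrix(NA_real_, n, 3L)
  Tv[matched, ] <- as.matrix(
    cmap$pairs[m[matched], c("T.x", "T.y", "T.z")])
  if (length(matched) < n) {
    for (c3 in 1:3)
      Tv[, c3] <- stats::approx(matched, Tv[matched, c3],
                                xout = seq_len(n), rule = 2L)$y
  }
  out <- fu_coarse
  for (i in seq_len(n)) {
    ring <- apply_transform(transform, fu_coarse$rings[i, , ])
    out$rings[i, , ] <- sweep(ring, 2L, Tv[i, ], `+`)
  }
  out
}
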