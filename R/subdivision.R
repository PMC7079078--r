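# Hexagonal-ring coarse meshes and Loop subdivision with stable vertex
# ancestry. The coarse mesh is the carrier of all correspondences:
# lumen<->wall and baseline<->follow-up surfaces are refined from the same
# coarse mesh, so equal ancestry ids identify corresponding points.

#' Build a hexagonal-ring coarse mesh along a centerline
#'
#' One hexagon of circumradius `radius` per centerline point, placed in
#' the plane normal to the local tangent. Ring azimuth is propagated by
#' rotation-minimizing frames (parallel transport) so consecutive rings do
#' not twist against each other.
#'
#' @param cl a (resampled) [extract_centerline()] result.
#' @param radius hexagon circumradius in mm; must be small enough that
#'   the tube starts inside the lumen.
#' @return An object of class `hex_ring_mesh`: `rings` (n x 6 x 3 array),
#'   `stations` (centerline arclength per ring, mm), `branch`, `radius`.
#' @export
build_coarse_mesh <- function(cl, radius) {
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(cl$points)
  frames <- rmf_frames(cl$points)
  theta <- (0:5) * pi / 3
  rings <- array(0, c(n, 6L, 3L))
  for (i in seq_len(n)) {
    hexv <- radius * (outer(cos(theta), frames$e1[i, ]) +
                        outer(sin(theta), frames$e2[i, ]))
    rings[i, , ] <- sweep(hexv, 2L, cl$points[i, ], `+`)
  }
  structure(list(rings = rings, stations = cl$arclengths,
                 branch = cl$branch, radius = radius),
            class = "hex_ring_mesh")
}

# Assemble the coarse hex-ring mesh into an indexed triangle mesh with
# end caps (closed surface, so Loop needs no boundary rules). Vertex
# order: ring-major (ring 1 verts 1..6, ring 2, ...), then the two cap
# centers.
coarse_to_trimesh <- function(mesh) {
  n <- dim(mesh$rings)[1L]
  V <- matrix(0, n * 6L, 3L)
  for (i in seq_len(n)) V[(i - 1L) * 6L + 1:6, ] <- mesh$rings[i, , ]
  idx <- function(i, j) (i - 1L) * 6L + ((j - 1L) %% 6L) + 1L
  faces <- vector("list", n + 1L)
  for (i in seq_len(n - 1L)) {
    j <- 1:6
    a <- idx(i, j); b <- idx(i, j + 1L)
    c2 <- idx(i + 1L, j + 1L); d <- idx(i + 1L, j)
    faces[[i]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  cap0 <- n * 6L + 1L; cap1 <- n * 6L + 2L
  V <- rbind(V, colMeans(mesh$rings[1L, , ]), colMeans(mesh$rings[n, , ]))
  j <- 1:6
  faces[[n]] <- cbind(rep(cap0, 6L), idx(1L, j + 1L), idx(1L, j))
  faces[[n + 1L]] <- cbind(rep(cap1, 6L), idx(n, j), idx(n, j + 1L))
  F <- do.call(rbind, faces)
  dimnames(F) <- NULL
  ancestry <- c(paste0("r", rep(seq_len(n), each = 6L), ".",
                       rep(1:6, n)), "cap0", "cap1")
  ring_coord <- c(rep(seq_len(n), each = 6L), 1L, n)
  is_cap <- c(rep(FALSE, n * 6L), TRUE, TRUE)
  list(vertices = V, faces = F, ancestry = ancestry,
       ring_coord = as.numeric(ring_coord), is_cap = is_cap)
}

# One round of Loop subdivision on a closed triangle mesh, propagating
# ancestry ids, fractional ring coordinates and cap flags.
loop_once <- function(V, F, ancestry, ring_coord, is_cap) {
  nv <- nrow(V); nf <- nrow(F)
  ek <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  opp <- c(F[, 3L], F[, 1L], F[, 2L])
  lo <- pmin(ek[, 1L], ek[, 2L]); hi <- pmax(ek[, 1L], ek[, 2L])
  key <- (lo - 1) * nv + hi
  ueid <- match(key, unique(key))
  ne <- max(ueid)
  # unique() preserves first-occurrence order, so ueid values at first
  # occurrences are already 1..ne in order
  first <- !duplicated(ueid)
  ea <- lo[first]; eb <- hi[first]
  # opposite vertices of the (exactly two) faces at each edge
  o <- order(ueid)
  cnt <- tabulate(ueid, ne)
  if (any(cnt != 2L))
    stop("mesh is not closed: ", sum(cnt != 2L), " boundary/odd edges")
  pos <- cumsum(c(0L, cnt[-ne]))
  opp_sorted <- opp[o]
  opp1 <- opp_sorted[pos + 1L]
  opp2 <- opp_sorted[pos + 2L]
  # odd (edge) vertices
  Ve <- 0.375 * (V[ea, , drop = FALSE] + V[eb, , drop = FALSE]) +
    0.125 * (V[opp1, , drop = FALSE] + V[opp2, , drop = FALSE])
  a1 <- ancestry[ea]; a2 <- ancestry[eb]
  anc_e <- ifelse(a1 < a2, paste0("[", a1, "|", a2, "]"),
                  paste0("[", a2, "|", a1, "]"))
  ring_e <- (ring_coord[ea] + ring_coord[eb]) / 2
  cap_e <- is_cap[ea] | is_cap[eb]
  # even vertices: Loop's valence-dependent smoothing mask
  val <- tabulate(c(ea, eb), nv)
  beta <- (1 / val) * (0.625 - (0.375 + 0.25 * cos(2 * pi / val))^2)
  nbr_sum <- rowsum(rbind(V[eb, , drop = FALSE], V[ea, , drop = FALSE]),
                    c(ea, eb), reorder = FALSE)
  nbr_sum <- nbr_sum[match(seq_len(nv), as.integer(rownames(nbr_sum))), ,
                     drop = FALSE]
  Vv <- (1 - val * beta) * V + beta * nbr_sum
  # new faces: 4 per parent face, consistent winding
  eid <- matrix(ueid, nf, 3L)  # columns: edge(1,2), edge(2,3), edge(3,1)
  m12 <- nv + eid[, 1L]; m23 <- nv + eid[, 2L]; m31 <- nv + eid[, 3L]
  Fnew <- rbind(cbind(F[, 1L], m12, m31),
                cbind(F[, 2L], m23, m12),
                cbind(F[, 3L], m31, m23),
                cbind(m12, m23, m31))
  list(vertices = rbind(Vv, Ve), faces = Fnew,
       ancestry = c(ancestry, anc_e),
       ring_coord = c(ring_coord, ring_e),
       is_cap = c(is_cap, cap_e))
}

#' Refine a coarse mesh into a subdivision surface
#'
#' Applies Loop (triangle) subdivision `levels` times to the triangulated
#' hex-ring tube (with end caps). Every vertex carries a stable ancestry
#' id derived from its coarse-mesh parents, a fractional ring coordinate
#' (axial position in ring units) and a cap flag; two surfaces refined
#' from topologically identical coarse meshes at the same level have
#' identical ancestry id sets, which is what makes per-vertex comparison
#' across surfaces possible.
#'
#' @param mesh a [build_coarse_mesh()] result.
#' @param levels subdivision depth (>= 1); each level multiplies the face
#'   count by 4.
#' @return An object of class `subdiv_surface` with fields `vertices`,
#'   `faces`, `ancestry`, `ring_coord`, `is_cap`, `level`, `stations`,
#'   `branch`.
#' @export
subdivide <- function(mesh, levels = 2L) {
  stopifnot(inherits(mesh, "hex_ring_mesh"), levels >= 1L)
  tm <- coarse_to_trimesh(mesh)
  for (l in seq_len(levels))
    tm <- loop_once(tm$vertices, tm$faces, tm$ancestry, tm$ring_coord,
                    tm$is_cap)
  structure(list(vertices = tm$vertices, faces = tm$faces,
                 ancestry = tm$ancestry, ring_coord = tm$ring_coord,
                 is_cap = tm$is_cap, level = as.integer(levels),
                 stations = mesh$stations, branch = mesh$branch),
            class = "subdiv_surface")
}

#' @export
print.subdiv_surface <- function(x, ...) {
  cat(sprintf("subdiv_surface '%s': %d vertices, %d faces (level %d)\n",
              x$branch, nrow(x$vertices), nrow(x$faces), x$level))
  invisible(x)
}

#' Area-weighted vertex normals of a triangle mesh
#'
#' @param V n x 3 vertex matrix.
#' @param F m x 3 face index matrix (outward winding).
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(V, F) {
  fn <- cross3_rows(V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE],
                    V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE])
  acc <- rowsum(rbind(fn, fn, fn), c(F[, 1L], F[, 2L], F[, 3L]),
                reorder = FALSE)
  acc <- acc[match(seq_len(nrow(V)), as.integer(rownames(acc))), ,
             drop = FALSE]
  acc[is.na(acc[, 1L]), ] <- 0
  nrm <- row_norms(acc)
  nrm[nrm < 1e-12] <- 1
  acc / nrm
}

# Row-normalised sparse vertex adjacency (for umbrella-Laplacian
# smoothing: L(V) = A V - V). When `drop_to` is given, neighbours NOT in
# `drop_to` are excluded from the averaging (rows renormalised), so e.g.
# tube vertices can be smoothed without being dragged by cap vertices.
adjacency_operator <- function(nv, F, drop_to = NULL) {
  ek <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  lo <- pmin(ek[, 1L], ek[, 2L]); hi <- pmax(ek[, 1L], ek[, 2L])
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  i <- c(lo[keep], hi[keep]); j <- c(hi[keep], lo[keep])
  if (!is.null(drop_to)) {
    ok <- drop_to[j]
    i <- i[ok]; j <- j[ok]
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  Matrix::Diagonal(x = 1 / deg) %*% A
}
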