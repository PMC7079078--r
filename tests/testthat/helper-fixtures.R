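# Shared fixtures, built in code and memoised per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# A small, fast three-branch tree for unit tests.
small_config <- function(points = 48L) {
  tree_config(branches = list(
    list(name = "RCA", length = 20, prox_radius = 1.8, dist_radius = 1.4,
         wall_offset = 0.5, curvature = 1 / 90, bend_amp = 0.8),
    list(name = "LAD", length = 16, prox_radius = 1.6, dist_radius = 1.3,
         wall_offset = 0.5, curvature = 1 / 110, bend_amp = 0.6),
    list(name = "LCx", length = 14, prox_radius = 1.6, dist_radius = 1.3,
         wall_offset = 0.5, curvature = 1 / 100, bend_amp = 0.5)),
    points_per_contour = points)
}

small_tree <- function() memo("small_tree", generate_tree(small_config()))

# A straight tube along +z with circular lumen/wall contours of constant
# radii: the analytic annulus fixture.
straight_branch <- function(r_lumen = 1.5, r_wall = 2.0, length = 10,
                            spacing = 0.5, K = 48L, name = "TUBE") {
  s <- seq(0, length, by = spacing)
  theta <- (seq_len(K) - 1L) * 2 * pi / K
  ring <- cbind(cos(theta), sin(theta), 0)
  lumen <- lapply(s, function(z)
    planar_contour(c(0, 0, z), c(0, 0, 1),
                   sweep(r_lumen * ring, 2L, c(0, 0, z), `+`),
                   validate = FALSE))
  wall <- lapply(s, function(z)
    planar_contour(c(0, 0, z), c(0, 0, 1),
                   sweep(r_wall * ring, 2L, c(0, 0, z), `+`),
                   validate = FALSE))
  vessel_branch(name, lumen, wall, validate = FALSE)
}

# Regular K-gon planar contour in the z = z0 plane.
circle_contour <- function(r, center = c(0, 0, 0), K = 12L) {
  theta <- (seq_len(K) - 1L) * 2 * pi / K
  planar_contour(center, c(0, 0, 1),
                 sweep(cbind(r * cos(theta), r * sin(theta), 0), 2L,
                       center, `+`))
}

# Fitted annulus surfaces (r = 1.5, R = 2.0), shared across tests.
annulus_fit <- function() memo("annulus_fit", {
  br <- straight_branch()
  cl <- resample_centerline(extract_centerline(br))
  coarse <- build_coarse_mesh(cl, 0.75)
  fit_lumen_then_wall(coarse, contour_stack(br, "lumen"),
                      contour_stack(br, "wall"))
})

expect_all_lt <- function(x, bound) expect_lt(max(x), bound)
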