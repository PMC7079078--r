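test_that("hex-ring coarse meshes sit on the centerline without twist", {
  line <- structure(list(branch = "S",
                         points = cbind(0, 0, seq(0, 2, by = 0.5)),
                         arclengths = seq(0, 2, by = 0.5),
                         distance_to_ostium = 0), class = "centerline")
  mesh <- build_coarse_mesh(line, 1.2)
  expect_equal(dim(mesh$rings), c(5L, 6L, 3L))
  # every ring vertex is exactly one circumradius from its center
  for (i in 1:5) {
    d <- sqrt(rowSums(sweep(mesh$rings[i, , ], 2L, line$points[i, ])^2))
    expect_equal(d, rep(1.2, 6L), tolerance = 1e-12)
  }
  expect_error(build_coarse_mesh(line, 0), "positive")

  # U-shaped centerline: parallel transport keeps ring twist below 5 deg
  phi <- seq(0, pi, length.out = 61L)
  u <- structure(list(branch = "U",
                      points = cbind(10 * cos(phi), 10 * sin(phi), 0.02 * phi),
                      arclengths = c(0, cumsum(sqrt(rowSums(
                        diff(cbind(10 * cos(phi), 10 * sin(phi), 0.02 * phi))^2)))),
                      distance_to_ostium = 0), class = "centerline")
  um <- build_coarse_mesh(u, 1)
  twists <- vapply(seq_len(60L), function(i) {
    c1 <- colMeans(um$rings[i, , ]); c2 <- colMeans(um$rings[i + 1L, , ])
    v1 <- um$rings[i, 1L, ] - c1; v2 <- um$rings[i + 1L, 1L, ] - c2
    # angle between first-vertex directions after removing the tangent bend
    acos(pmin(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))) * 180 / pi
  }, 0)
  expect_all_lt(twists, 5)
})

test_that("Loop subdivision quadruples faces and keeps unique ancestry", {
  line <- structure(list(branch = "S",
                         points = cbind(0, 0, seq(0, 3, by = 0.5)),
                         arclengths = seq(0, 3, by = 0.5),
                         distance_to_ostium = 0), class = "centerline")
  mesh <- build_coarse_mesh(line, 1)
  tm <- plaquediff:::coarse_to_trimesh(mesh)
  F0 <- nrow(tm$faces)
  for (lev in 1:3) {
    s <- subdivide(mesh, lev)
    expect_equal(nrow(s$faces), F0 * 4L^lev)
    expect_false(anyDuplicated(s$ancestry) > 0L)
    # closed 2-manifold: every edge shared by exactly two faces
    ek <- rbind(s$faces[, 1:2], s$faces[, 2:3], s$faces[, c(3, 1)])
    key <- paste(pmin(ek[, 1L], ek[, 2L]), pmax(ek[, 1L], ek[, 2L]))
    expect_true(all(table(key) == 2L))
  }

  # identical topology => identical ancestry sets, regardless of geometry
  line2 <- line
  line2$points <- sweep(line$points, 2L, c(5, -2, 1), `+`)
  mesh2 <- build_coarse_mesh(line2, 0.7)
  expect_setequal(subdivide(mesh, 2L)$ancestry, subdivide(mesh2, 2L)$ancestry)
})

test_that("repeated subdivision rounds a hex tube toward its limit", {
  line <- structure(list(branch = "S",
                         points = cbind(0, 0, seq(0, 4, by = 0.5)),
                         arclengths = seq(0, 4, by = 0.5),
                         distance_to_ostium = 0), class = "centerline")
  mesh <- build_coarse_mesh(line, 1)
  spread <- vapply(1:3, function(lev) {
    s <- subdivide(mesh, lev)
    mid <- !s$is_cap & s$ring_coord > 3 & s$ring_coord < 7
    r <- sqrt(rowSums(s$vertices[mid, 1:2]^2))
    max(r) - min(r)
  }, 0)
  expect_true(all(diff(spread) < 0))
})

test_that("fitting reaches analytic cylinders and preserves ancestry", {
  br <- straight_branch(2.0, 2.5, length = 8)
  cl <- resample_centerline(extract_centerline(br))
  coarse <- build_coarse_mesh(cl, 1.0)
  init <- subdivide(coarse, 2L)
  lum <- contour_stack(br, "lumen")
  fit1 <- fit_to_contours(init, lum)
  expect_true(fit1$fit$converged)
  expect_lt(fit1$fit$rms, 0.05)
  # fitted radius 2.00 +/- 0.02 at every tube vertex
  r <- sqrt(rowSums(fit1$vertices[!fit1$is_cap, 1:2]^2))
  expect_true(all(abs(r - 2.0) < 0.02))
  # ancestry untouched by fitting
  expect_identical(fit1$ancestry, init$ancestry)

  # fixed point: refitting an already fitted surface barely moves the
  # tube (residual forces are below force_tol, so any step is tiny)
  fit2 <- fit_to_contours(fit1, lum)
  expect_equal(fit2$fit$iterations, 1L)
  mv <- sqrt(rowSums((fit2$vertices - fit1$vertices)^2))
  expect_lt(max(mv[!fit1$is_cap]), 0.02)
})

test_that("lumen-then-wall fitting gives the annulus thickness", {
  fits <- annulus_fit()
  expect_identical(fits$lumen$ancestry, fits$wall$ancestry)
  th <- compute_thickness(fits$lumen, fits$wall)
  tube <- !th$is_cap
  expect_true(all(abs(th$thickness[tube] - 0.5) < 0.02))

  # coincident lumen/wall targets: wall surface equals lumen surface
  br0 <- straight_branch(1.5, 1.5, length = 6)
  cl0 <- resample_centerline(extract_centerline(br0))
  f0 <- fit_lumen_then_wall(build_coarse_mesh(cl0, 0.75),
                            contour_stack(br0, "lumen"),
                            contour_stack(br0, "wall"))
  th0 <- compute_thickness(f0$lumen, f0$wall)
  expect_all_lt(th0$thickness[!th0$is_cap], 0.02)
})

test_that("fitting a rigidly moved problem gives the moved solution", {
  # rotation about the x-axis keeps the frame seed equivariant
  br <- straight_branch(1.6, 2.1, length = 6)
  cl <- resample_centerline(extract_centerline(br))
  fit <- fit_lumen_then_wall(build_coarse_mesh(cl, 0.8),
                             contour_stack(br, "lumen"),
                             contour_stack(br, "wall"))
  R <- plaquediff:::rotation_axis_angle(c(1, 0, 0), 25 * pi / 180)
  tv <- c(4, -3, 7)
  mv <- function(p) sweep(p %*% t(R), 2L, tv, `+`)
  brT <- br
  for (i in seq_along(br$lumen)) {
    for (side in c("lumen", "wall")) {
      brT[[side]][[i]]$points <- mv(br[[side]][[i]]$points)
      brT[[side]][[i]]$center <- drop(R %*% br[[side]][[i]]$center) + tv
      brT[[side]][[i]]$normal <- drop(R %*% br[[side]][[i]]$normal)
    }
  }
  clT <- resample_centerline(extract_centerline(brT))
  fitT <- fit_lumen_then_wall(build_coarse_mesh(clT, 0.8),
                              contour_stack(brT, "lumen"),
                              contour_stack(brT, "wall"))
  expect_lt(max(abs(fitT$lumen$vertices - mv(fit$lumen$vertices))), 1e-3)
  expect_lt(max(abs(fitT$wall$vertices - mv(fit$wall$vertices))), 1e-3)
})

test_that("coarse-mesh mapping applies per-ring translations", {
  line <- structure(list(branch = "S",
                         points = cbind(0, 0, c(0, 0.5, 1, 1.5)),
                         arclengths = c(0, 0.5, 1, 1.5),
                         distance_to_ostium = 0), class = "centerline")
  mesh <- build_coarse_mesh(line, 1)
  # identity transform + zero T_vec: unchanged
  cmap0 <- structure(list(
    pairs = data.frame(bl = 1:4, fu = 1:4, T.x = 0, T.y = 0, T.z = 0),
    unmatched_bl = integer(0L), unmatched_fu = integer(0L)),
    class = "correspondence_map")
  m0 <- map_coarse_mesh(mesh, cmap0, rigid_transform())
  expect_equal(m0$rings, mesh$rings, tolerance = 1e-12)

  # uniform T_vec (1,0,0): every ring vertex shifts by (1,0,0)
  cmap1 <- cmap0
  cmap1$pairs$T.x <- 1
  m1 <- map_coarse_mesh(mesh, cmap1, rigid_transform())
  expect_equal(m1$rings[, , 1L], mesh$rings[, , 1L] + 1, tolerance = 1e-12)
  expect_equal(m1$rings[, , 2:3], mesh$rings[, , 2:3], tolerance = 1e-12)

  # unmatched interior ring: T_vec linearly interpolated along the index
  cmap2 <- cmap0
  cmap2$pairs <- cmap2$pairs[-2L, ]
  cmap2$pairs$T.x <- c(0, 2, 2)
  cmap2$unmatched_fu <- 2L
  m2 <- map_coarse_mesh(mesh, cmap2, rigid_transform())
  expect_equal(m2$rings[2L, , 1L], mesh$rings[2L, , 1L] + 1,
               tolerance = 1e-12)

  cmap3 <- cmap0
  cmap3$pairs <- cmap3$pairs[0L, ]
  expect_error(map_coarse_mesh(mesh, cmap3, rigid_transform()),
               "no matched rings")
})
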