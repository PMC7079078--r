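test_that("generated trees have the configured sampling and geometry", {
  cfg <- tree_config(branches = list(
    list(name = "A", length = 60, prox_radius = 1.8, dist_radius = 1.3,
         wall_offset = 0.3, curvature = 1 / 100, bend_amp = 1),
    list(name = "B", length = 60, prox_radius = 1.8, dist_radius = 1.3,
         wall_offset = 0.3, curvature = 1 / 100, bend_amp = 1),
    list(name = "C", length = 60, prox_radius = 1.8, dist_radius = 1.3,
         wall_offset = 0.3, curvature = 1 / 100, bend_amp = 1)),
    spacing = 0.5)
  tree <- generate_tree(cfg)
  # length/spacing + 1 contour pairs per branch
  for (br in tree$branches) expect_length(br$lumen, 121L)

  # determinism: same config twice gives identical trees
  tree2 <- generate_tree(cfg)
  expect_identical(tree, tree2)

  # analytic annulus: every wall-to-lumen radius gap equals wall_offset
  for (br in tree$branches)
    for (i in c(1L, 60L, 121L)) {
      rl <- sqrt(rowSums(sweep(br$lumen[[i]]$points, 2L,
                               br$lumen[[i]]$center)^2))
      rw <- sqrt(rowSums(sweep(br$wall[[i]]$points, 2L,
                               br$wall[[i]]$center)^2))
      expect_equal(rw - rl, rep(0.3, length(rl)), tolerance = 1e-9)
    }
  expect_silent(validate_tree(tree))
})

test_that("plaque edits act only inside the window with known amplitude", {
  tree <- small_tree()
  sp <- plaque_spec("RCA", 10, 4, dR_lumen = -0.50)
  res <- apply_plaque(tree, sp)
  edited <- res$tree
  s <- plaquediff:::branch_arclengths(tree$branches$RCA)

  # contour count conserved; outside the window bit-identical
  expect_length(edited$branches$RCA$lumen, length(tree$branches$RCA$lumen))
  outside <- which(abs(s - 10) > 2 + 1e-9)
  for (i in outside) {
    expect_identical(edited$branches$RCA$lumen[[i]],
                     tree$branches$RCA$lumen[[i]])
    expect_identical(edited$branches$RCA$wall[[i]],
                     tree$branches$RCA$wall[[i]])
  }

  # per-contour radius change equals the boxcar profile with the
  # half-amplitude transition at each window edge
  expected <- -0.5 * plaquediff:::.edit_amplitude(s, 10, 4, 0.5)
  expect_true(any(abs(expected + 0.25) < 1e-9))  # transition contours exist
  for (i in which(expected != 0)) {
    dr <- sqrt(rowSums(sweep(edited$branches$RCA$lumen[[i]]$points, 2L,
                             edited$branches$RCA$lumen[[i]]$center)^2)) -
      sqrt(rowSums(sweep(tree$branches$RCA$lumen[[i]]$points, 2L,
                         tree$branches$RCA$lumen[[i]]$center)^2))
    expect_equal(dr, rep(expected[i], length(dr)), tolerance = 1e-12)
  }

  # ground truth: created value inside, zero outside (pointwise)
  expect_equal(res$truth[[1L]]$created, 0.5)
  interior <- which(abs(expected + 0.5) < 1e-9)
  expect_equal(truth_at(res$truth, "RCA", s[interior]),
               rep(0.5, length(interior)))
  expect_equal(truth_at(res$truth, "RCA", s[outside]),
               rep(0, length(outside)))

  # identity edit returns the tree unchanged
  res0 <- apply_plaque(tree, plaque_spec("RCA", 10, 4))
  expect_identical(res0$tree, tree)

  # combined +0.50/+0.50 edit creates zero difference everywhere
  res10 <- apply_plaque(tree, plaque_spec("RCA", 10, 4, dR_lumen = 0.5,
                                          dR_wall = 0.5))
  expect_equal(max(abs(truth_at(res10$truth, "RCA", s))), 0)

  # infeasible edit (lumen below 0.2 mm) is refused
  expect_error(apply_plaque(tree, plaque_spec("RCA", 10, 4,
                                              dR_lumen = -1.6)),
               "0.2 mm")
})

test_that("follow-up perturbation is rigid and its jitter calibrated", {
  tree <- small_tree()
  # identity pose, no noise: unchanged
  expect_identical(make_followup(tree), tree)

  # rigid isometry: all pairwise distances preserved
  fu <- make_followup(tree, rotation = 10, axis = c(0.3, 1, 0.1),
                      translation = c(5, 3, -2))
  p0 <- tree$branches$RCA$lumen[[3L]]$points
  p1 <- fu$branches$RCA$lumen[[3L]]$points
  expect_lt(max(abs(dist(p0) - dist(p1))), 1e-9)
  q0 <- do.call(rbind, lapply(tree$branches$LAD$wall, `[[`, "points"))
  q1 <- do.call(rbind, lapply(fu$branches$LAD$wall, `[[`, "points"))
  idx <- seq(1L, nrow(q0), by = 7L)
  expect_lt(max(abs(dist(q0[idx, ]) - dist(q1[idx, ]))), 1e-9)

  # half-normal jitter: mean radial displacement ~ sd * sqrt(2/pi)
  tree <- generate_tree(small_config(points = 64L))
  fuj <- make_followup(tree, noise_sd = 0.05, seed = 11L)
  disp <- unlist(lapply(names(tree$branches), function(bn)
    lapply(seq_along(tree$branches[[bn]]$lumen), function(i)
      c(sqrt(rowSums((fuj$branches[[bn]]$lumen[[i]]$points -
                        tree$branches[[bn]]$lumen[[i]]$points)^2)),
        sqrt(rowSums((fuj$branches[[bn]]$wall[[i]]$points -
                        tree$branches[[bn]]$wall[[i]]$points)^2))))))
  expect_gt(length(disp), 1e4)
  expect_equal(mean(disp), 0.05 * sqrt(2 / pi), tolerance = 0.02)

  # determinism of the jitter
  fuj2 <- make_followup(tree, noise_sd = 0.05, seed = 11L)
  expect_identical(fuj, fuj2)
})

test_that("markers land at arclength fractions of every branch", {
  tree <- small_tree()
  m <- place_markers(tree, tree)
  expect_equal(nrow(m), 15L)  # 5 per branch
  expect_setequal(unique(substr(m$label, 1L, 1L)),
                  c("s", "p", "m", "d", "e"))
  # identity follow-up: paired coordinates coincide
  expect_equal(as.matrix(m[, c("bl.x", "bl.y", "bl.z")]),
               as.matrix(m[, c("fu.x", "fu.y", "fu.z")]),
               ignore_attr = TRUE)
  # start marker sits at the proximal contour center
  s_rca <- m[m$label == "sRCA", ]
  expect_equal(as.numeric(s_rca[, c("bl.x", "bl.y", "bl.z")]),
               plaquediff:::extract_centerline(tree$branches$RCA)$points[1L, ],
               tolerance = 0.05)
})

test_that("the ten-case artificial suite matches its construction table", {
  cases <- table2_suite(small_config(), seed = 3L, noise_sd = 0)
  expect_length(cases, 10L)
  expect_equal(vapply(cases, `[[`, 0L, "no"), 1:10)

  L <- vapply(cases, function(cs) cs$truth[[1L]]$L, 0)
  expect_equal(L[1:3], c(4, 6, 2))

  # case 3: edit window spans exactly 2 mm
  w3 <- cases[[3L]]$truth[[1L]]$window
  expect_equal(diff(w3), 2)

  # case 7: three disjoint windows on one branch
  expect_length(cases[[7L]]$truth, 3L)
  wins <- t(vapply(cases[[7L]]$truth, `[[`, numeric(2L), "window"))
  expect_true(all(wins[-1L, 1L] > wins[-3L, 2L]))
  expect_equal(unique(vapply(cases[[7L]]$truth, `[[`, "", "branch")), "RCA")

  # case 8: one plaque per branch
  expect_setequal(vapply(cases[[8L]]$truth, `[[`, "", "branch"),
                  c("RCA", "LAD", "LCx"))

  # created values follow the table; case 10 is the null
  created <- vapply(cases, function(cs) cs$truth[[1L]]$created, 0)
  expect_equal(created, c(0.5, 0.5, 0.5, 0.25, 1, -0.5, 0.5, 0.5, 0.5, 0))

  # each follow-up differs from baseline by one global rigid map
  cs <- cases[[1L]]
  p0 <- do.call(rbind, lapply(cs$bl$branches$RCA$lumen[1:5], `[[`, "points"))
  p1 <- do.call(rbind, lapply(cs$fu$branches$RCA$lumen[1:5], `[[`, "points"))
  expect_lt(max(abs(dist(p0) - dist(p1))), 1e-9)
})
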