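test_that("planar_contour enforces its geometric invariants", {
  ct <- circle_contour(1.5)
  expect_s3_class(ct, "planar_contour")

  # clockwise input is normalised to CCW about the normal
  cw <- circle_contour(1.5)
  cw2 <- planar_contour(cw$center, cw$normal,
                        cw$points[rev(seq_len(nrow(cw$points))), ])
  expect_equal(cw2$points, cw$points)

  # too few points
  theta <- (0:5) * pi / 3
  expect_error(planar_contour(c(0, 0, 0), c(0, 0, 1),
                              cbind(cos(theta), sin(theta), 0)),
               "at least 8")

  # non-coplanar points
  pts <- circle_contour(1)$points
  pts[3L, 3L] <- 0.01
  expect_error(planar_contour(c(0, 0, 0), c(0, 0, 1), pts), "plane")

  # center outside the polygon
  expect_error(planar_contour(c(5, 0, 0), c(0, 0, 1),
                              circle_contour(1)$points), "outside")

  # self-intersecting (bowtie) polygon
  t8 <- seq(0, 2 * pi, length.out = 9L)[-9L]
  bow <- cbind(cos(t8), sin(t8) * rep(c(1, -1), each = 4L), 0)
  expect_error(planar_contour(c(0, 0, 0), c(0, 0, 1), bow),
               "self-intersecting|outside|CCW")
})

test_that("polygon containment handles nesting, coincidence and reversal", {
  inner <- circle_contour(1)
  outer <- circle_contour(2)
  expect_true(polygon_contains(outer, inner))
  expect_true(polygon_contains(outer, outer))  # coincidence allowed
  expect_false(polygon_contains(inner, outer))
  # non-coplanar rejection
  shifted <- circle_contour(1, center = c(0, 0, 3))
  expect_error(polygon_contains(outer, shifted), "coplanar")
})

test_that("branch and tree validation reject broken invariants", {
  br <- straight_branch(1.5, 2.0, length = 3)
  expect_silent(validate_branch(br))

  # wall inside lumen
  swapped <- vessel_branch(br$name, br$wall, br$lumen, validate = FALSE)
  expect_error(validate_branch(swapped), "contain")

  # lumen/wall center mismatch
  br2 <- br
  br2$wall[[2L]]$center <- br2$wall[[2L]]$center + c(0.5, 0, 0)
  expect_error(validate_branch(br2), "share center")

  # coincident consecutive centers
  br3 <- br
  br3$lumen[[2L]] <- br3$lumen[[1L]]
  br3$wall[[2L]] <- br3$wall[[1L]]
  expect_error(validate_branch(br3), "coincide")

  # duplicate branch names / empty tree
  expect_error(coronary_tree(list(br, br), c(0, 0, 0)), "unique")
  expect_error(coronary_tree(list(), c(0, 0, 0)), "at least one")
})

test_that("JSON contour files round-trip exactly and validate on read", {
  tree <- generate_tree(small_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, path)
  tree2 <- read_tree(path)
  expect_equal(length(tree2$branches), 3L)
  expect_equal(length(tree2$branches$RCA$lumen),
               length(tree$branches$RCA$lumen))
  for (bn in names(tree$branches))
    for (i in seq_along(tree$branches[[bn]]$lumen)) {
      expect_lt(max(abs(tree2$branches[[bn]]$lumen[[i]]$points -
                          tree$branches[[bn]]$lumen[[i]]$points)), 1e-9)
      expect_lt(max(abs(tree2$branches[[bn]]$wall[[i]]$points -
                          tree$branches[[bn]]$wall[[i]]$points)), 1e-9)
    }
  expect_lt(max(abs(tree2$ostium - tree$ostium)), 1e-9)

  # a tree whose wall lies inside its lumen is rejected before writing
  bad <- tree
  bad$branches$RCA <- vessel_branch("RCA", bad$branches$RCA$wall,
                                    bad$branches$RCA$lumen,
                                    validate = FALSE)
  path2 <- withr::local_tempfile(fileext = ".json")
  expect_error(write_tree(bad, path2), "contain")

  # a FILE with swapped lumen/wall polygons fails read-time validation,
  # naming the offending branch
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  lum <- doc$branches$contours[[1L]]$lumen[[1L]]
  doc$branches$contours[[1L]]$lumen[[1L]] <-
    doc$branches$contours[[1L]]$wall[[1L]]
  doc$branches$contours[[1L]]$wall[[1L]] <- lum
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path3, auto_unbox = TRUE, digits = NA)
  expect_error(read_tree(path3), "RCA")

  expect_error(read_tree(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("round-trip identity holds across many generated trees", {
  path <- withr::local_tempfile(fileext = ".json")
  for (seed in c(7L, 21L, 99L)) {
    cfg <- small_config()
    tree <- generate_tree(cfg)
    tree <- make_followup(tree, rotation = seed %% 13, axis = c(1, seed, 2),
                          translation = c(seed, -1, 0.5), noise_sd = 0.02,
                          seed = seed)
    write_tree(tree, path)
    tree2 <- read_tree(path)
    for (bn in names(tree$branches))
      expect_lt(max(abs(tree2$branches[[bn]]$lumen[[5L]]$points -
                          tree$branches[[bn]]$lumen[[5L]]$points)), 1e-9)
  }
})

test_that("marker sets validate labels and round-trip through JSON", {
  m <- marker_set(c("sRCA", "mLAD"), rbind(c(0, 0, 0), c(1, 1, 1)),
                  rbind(c(0, 0, 1), c(1, 1, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  write_markers(m, path)
  m2 <- read_markers(path)
  expect_equal(m2$label, m$label)
  expect_equal(as.matrix(m2[, -1L]), as.matrix(m[, -1L]), tolerance = 1e-12)
  expect_error(marker_set("xRCA", c(0, 0, 0), c(0, 0, 0)), "s/p/m/d/e")
})
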