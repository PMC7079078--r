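# Synthetic coronary-artery-tree generator: parametric multi-branch
# tubular trees with circular cross-sections, localized plaque edits with
# known ground-truth thickness change, and rigid follow-up perturbation.

#' Configuration for the synthetic tree generator
#'
#' The defaults describe a three-branch tree (RCA/LAD/LCx) with gently
#' curved C1 centerlines, linearly tapering circular lumina and a constant
#' concentric wall offset, sampled every 0.5 mm — the stand-in anatomy on
#' which the artificial baseline/follow-up validation suite is built.
#'
#' @param branches list of per-branch specs; each a list with `name`,
#'   `length` (mm), `prox_radius`/`dist_radius` (lumen, mm), `wall_offset`
#'   (mm), `curvature` (1/mm, arc curvature of the main bend) and
#'   `bend_amp` (mm, gentle out-of-plane bend amplitude).
#' @param spacing contour spacing along each branch (mm).
#' @param points_per_contour vertices per contour polygon (>= 8).
#' @param seed integer seed stored with the config; the base geometry is
#'   deterministic, the seed feeds stochastic follow-up perturbation.
#' @return An object of class `tree_config`.
#' @export
tree_config <- function(branches = NULL, spacing = 0.5,
                        points_per_contour = 48L, seed = 1L) {
  if (is.null(branches)) {
    branches <- list(
      list(name = "RCA", length = 60, prox_radius = 1.9, dist_radius = 1.3,
           wall_offset = 0.6, curvature = 1 / 90, bend_amp = 2.0),
      list(name = "LAD", length = 55, prox_radius = 1.8, dist_radius = 1.2,
           wall_offset = 0.6, curvature = 1 / 110, bend_amp = 1.5),
      list(name = "LCx", length = 45, prox_radius = 1.7, dist_radius = 1.2,
           wall_offset = 0.6, curvature = 1 / 100, bend_amp = 1.2))
  }
  stopifnot(spacing > 0, points_per_contour >= 8L)
  for (b in branches)
    stopifnot(b$length > 0, b$prox_radius > 0, b$dist_radius > 0,
              b$wall_offset >= 0)
  structure(list(branches = branches, spacing = spacing,
                 points_per_contour = as.integer(points_per_contour),
                 seed = as.integer(seed)),
            class = "tree_config")
}

# Branch take-off directions: roughly anatomical, well separated so that
# pooled-centerline registration cannot confuse branches.
.branch_frame <- function(idx) {
  dirs <- list(c(1, -0.3, -0.9), c(-0.6, 0.4, -0.9), c(-0.9, -0.5, -0.4),
               c(0.2, 0.9, -0.6), c(0.7, 0.7, 0.3))
  i <- ((idx - 1L) %% length(dirs)) + 1L
  d <- unit(dirs[[i]])
  b <- plane_basis(d)
  list(d = d, u = b$e1, w = b$e2)
}

#' Generate a synthetic coronary tree
#'
#' Each branch centerline is a planar circular arc with curvature
#' `curvature` plus a gentle out-of-plane cosine bend (C1 everywhere).
#' Cross-sections are circles of linearly tapering lumen radius with
#' concentric wall contours at `lumen radius + wall_offset`; contour
#' frames follow rotation-minimizing frames so polygons do not twist
#' along the vessel.
#'
#' @param config a [tree_config()].
#' @return A validated [coronary_tree()].
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "tree_config"))
  K <- config$points_per_contour
  theta <- (seq_len(K) - 1L) * 2 * pi / K
  branches <- vector("list", length(config$branches))
  for (bi in seq_along(config$branches)) {
    b <- config$branches[[bi]]
    fr <- .branch_frame(bi)
    s <- seq(0, b$length, by = config$spacing)
    if (abs(s[length(s)] - b$length) > 1e-9) s <- c(s, b$length)
    # planar arc in the (d, u) plane + out-of-plane bend along w
    Rc <- 1 / b$curvature
    ctr <- outer(Rc * sin(s / Rc), fr$d) +
      outer(Rc * (1 - cos(s / Rc)), fr$u) +
      outer(b$bend_amp * (1 - cos(pi * s / b$length)) / 2, fr$w)
    ctr <- sweep(ctr, 2L, c(0, 0, 0), `+`)
    frames <- rmf_frames(ctr)
    radius <- b$prox_radius + (b$dist_radius - b$prox_radius) * s / b$length
    lumen <- vector("list", length(s)); wall <- vector("list", length(s))
    for (i in seq_along(s)) {
      ring <- outer(cos(theta), frames$e1[i, ]) +
        outer(sin(theta), frames$e2[i, ])
      lu <- sweep(radius[i] * ring, 2L, ctr[i, ], `+`)
      wa <- sweep((radius[i] + b$wall_offset) * ring, 2L, ctr[i, ], `+`)
      lumen[[i]] <- planar_contour(ctr[i, ], frames$tangent[i, ], lu,
                                   validate = FALSE)
      wall[[i]] <- planar_contour(ctr[i, ], frames$tangent[i, ], wa,
                                  validate = FALSE)
    }
    branches[[bi]] <- vessel_branch(b$name, lumen, wall, validate = FALSE)
  }
  tree <- coronary_tree(branches, ostium = c(0, 0, 0), validate = FALSE)
  # tube self-intersection guard: ring radius must stay below the local
  # radius of curvature
  for (bi in seq_along(config$branches)) {
    b <- config$branches[[bi]]
    if (max(b$prox_radius, b$dist_radius) + b$wall_offset >= 1 / b$curvature)
      stop("infeasible geometry: branch '", b$name,
           "' tube radius exceeds its radius of curvature")
  }
  tree
}

#' Plaque edit specification
#'
#' Describes a localized plaque as radial edits of the lumen and/or wall
#' contours over an axial window, the machinery behind the artificial
#' dataset suite: a lumen radius decrease simulates plaque progression, a
#' lumen increase regression, a wall increase positive remodeling.
#'
#' @param branch branch name to edit.
#' @param s0 arclength of the plaque center from the branch start (mm).
#' @param L plaque length along the vessel (mm).
#' @param dR_lumen signed lumen radius change (mm); negative shrinks.
#' @param dR_wall signed wall radius change (mm).
#' @param angular_extent degrees of circumference affected; 360 =
#'   concentric. Eccentric edits get a cosine angular taper.
#' @param angular_center centre of the angular window (degrees, in the
#'   contour's local frame), for eccentric edits.
#' @return An object of class `plaque_spec`.
#' @export
plaque_spec <- function(branch, s0, L, dR_lumen = 0, dR_wall = 0,
                        angular_extent = 360, angular_center = 0) {
  stopifnot(L > 0, angular_extent > 0, angular_extent <= 360)
  structure(list(branch = branch, s0 = s0, L = L, dR_lumen = dR_lumen,
                 dR_wall = dR_wall, angular_extent = angular_extent,
                 angular_center = angular_center),
            class = "plaque_spec")
}

# Cumulative chord-length arclength of a branch's contour centers.
branch_arclengths <- function(branch) {
  centers <- t(vapply(branch$lumen, `[[`, numeric(3L), "center"))
  c(0, cumsum(row_norms(diff(centers))))
}

# Axial edit amplitude: boxcar over [s0-L/2, s0+L/2] with one
# half-amplitude transition contour at each end of the window.
.edit_amplitude <- function(s, s0, L, h) {
  a <- numeric(length(s))
  d <- abs(s - s0)
  # 1e-3 mm slack: chord-length stations deviate from nominal spacing by
  # ~1e-5 mm on curved branches, which must not drop the edge contour
  a[d <= L / 2 + 1e-3] <- 0.5
  a[d <= L / 2 - h + 1e-3] <- 1
  a
}

#' Apply a plaque edit to a tree
#'
#' Within the axial window `[s0 - L/2, s0 + L/2]` lumen contour points are
#' moved radially (in-plane, relative to the contour center) by
#' `dR_lumen` and wall points by `dR_wall`; the window's outermost contour
#' at each end gets half amplitude as the transition of the otherwise
#' abrupt edit. Contours outside the window are untouched. The returned
#' ground truth records the created thickness change
#' `dR_wall - dR_lumen` (positive = thickness increase) over the window.
#'
#' @param tree a [coronary_tree()].
#' @param spec a [plaque_spec()] (or list of them).
#' @return list with elements `tree` (edited copy) and `truth` (a
#'   `ground_truth_diff`: one record per spec with the edit window, the
#'   full-amplitude interior window, and the created difference in mm).
#' @export
apply_plaque <- function(tree, spec) {
  specs <- if (inherits(spec, "plaque_spec")) list(spec) else spec
  records <- vector("list", length(specs))
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    if (!sp$branch %in% names(tree$branches))
      stop("no branch named '", sp$branch, "'")
    br <- tree$branches[[sp$branch]]
    s <- branch_arclengths(br)
    h <- stats::median(diff(s))
    amp <- .edit_amplitude(s, sp$s0, sp$L, h)
    for (i in which(amp > 0)) {
      br$lumen[[i]] <- .edit_contour(br$lumen[[i]], amp[i] * sp$dR_lumen,
                                     sp$angular_extent, sp$angular_center)
      br$wall[[i]] <- .edit_contour(br$wall[[i]], amp[i] * sp$dR_wall,
                                    sp$angular_extent, sp$angular_center)
      rmin <- min(row_norms(sweep(br$lumen[[i]]$points, 2L,
                                  br$lumen[[i]]$center)))
      if (rmin <= 0.2)
        stop("plaque spec would shrink the lumen radius to ",
             sprintf("%.3f", rmin), " mm (<= 0.2 mm)")
    }
    tree$branches[[sp$branch]] <- br
    records[[si]] <- list(
      branch = sp$branch, s0 = sp$s0, L = sp$L,
      window = c(sp$s0 - sp$L / 2, sp$s0 + sp$L / 2),
      interior = c(sp$s0 - sp$L / 2 + h, sp$s0 + sp$L / 2 - h),
      created = sp$dR_wall - sp$dR_lumen,
      profile = data.frame(s = s, amplitude = amp))
  }
  validate_tree(tree)
  list(tree = tree, truth = structure(records, class = "ground_truth_diff"))
}

.edit_contour <- function(ct, dR, angular_extent, angular_center) {
  if (dR == 0) return(ct)
  d <- sweep(ct$points, 2L, ct$center)
  r <- row_norms(d)
  dirs <- d / r
  if (angular_extent >= 360) {
    w <- 1
  } else {
    b <- plane_basis(ct$normal)
    ang <- atan2(as.numeric(d %*% b$e2), as.numeric(d %*% b$e1)) * 180 / pi
    dth <- abs(((ang - angular_center + 180) %% 360) - 180)
    half <- angular_extent / 2
    w <- ifelse(dth <= half, 0.5 * (1 + cos(pi * dth / half)), 0)
  }
  ct$points <- ct$points + dirs * (dR * w)
  ct
}

#' Ground-truth thickness difference at arbitrary stations
#'
#' Evaluates the created per-location thickness change for a branch at the
#' given arclength stations (concentric edits).
#'
#' @param truth a `ground_truth_diff` from [apply_plaque()].
#' @param branch branch name.
#' @param s numeric vector of arclength stations (mm).
#' @return numeric vector of created thickness differences (mm).
#' @export
truth_at <- function(truth, branch, s) {
  out <- numeric(length(s))
  for (rec in truth) {
    if (rec$branch != branch) next
    h <- rec$window[2L] - rec$interior[2L]
    out <- out + rec$created * .edit_amplitude(s, rec$s0, rec$L, h)
  }
  out
}

#' Create a follow-up acquisition by rigid perturbation
#'
#' Applies one global rigid transform (simulating the independent scanner
#' coordinate frame of the second acquisition) and optional zero-mean
#' Gaussian radial jitter per contour point (simulating contour
#' delineation noise).
#'
#' @param tree a [coronary_tree()].
#' @param rotation rotation angle in degrees.
#' @param axis rotation axis (default `c(0, 0, 1)`).
#' @param translation length-3 translation (mm).
#' @param noise_sd radial jitter standard deviation (mm).
#' @param seed integer seed for the jitter.
#' @return A transformed [coronary_tree()].
#' @export
make_followup <- function(tree, rotation = 0, axis = c(0, 0, 1),
                          translation = c(0, 0, 0), noise_sd = 0,
                          seed = 1L) {
  stopifnot(noise_sd >= 0)
  R <- rotation_axis_angle(axis, rotation * pi / 180)
  tv <- as.numeric(translation)
  rng <- NULL
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  map_pt <- function(p) drop(R %*% p) + tv
  for (bn in names(tree$branches)) {
    br <- tree$branches[[bn]]
    for (i in seq_along(br$lumen)) {
      lum_r <- NULL
      for (side in c("lumen", "wall")) {
        ct <- br[[side]][[i]]
        pts <- ct$points
        if (noise_sd > 0) {
          d <- sweep(pts, 2L, ct$center)
          r <- row_norms(d)
          dirs <- d / r
          rn <- r + stats::rnorm(nrow(pts), 0, noise_sd)
          # delineation noise must not push the wall inside the lumen;
          # coinciding contours (zero thickness) are legal
          if (side == "wall" && !is.null(lum_r) &&
              length(lum_r) == length(rn))
            rn <- pmax(rn, lum_r)
          if (side == "lumen") lum_r <- rn
          pts <- sweep(dirs * rn, 2L, ct$center, `+`)
        }
        ct$points <- t(R %*% t(pts)) + matrix(tv, nrow(pts), 3L, byrow = TRUE)
        ct$center <- map_pt(ct$center)
        ct$normal <- drop(R %*% ct$normal)
        br[[side]][[i]] <- ct
      }
    }
    tree$branches[[bn]] <- br
  }
  tree$ostium <- map_pt(tree$ostium)
  tree
}

#' Place ground-truth marker pairs on a baseline/follow-up pair
#'
#' Markers are placed at arclength fractions 0, 0.25, 0.5, 0.75, 1 of each
#' branch (labels s-, p-, m-, d-, e- + branch name), interpolated along the
#' contour-center polylines. Because the follow-up derives from the
#' baseline by a rigid map, equal arclength fractions identify the same
#' material point.
#'
#' @param bl,fu baseline and follow-up [coronary_tree()] objects with
#'   matching branch sets.
#' @return A [marker_set()].
#' @export
place_markers <- function(bl, fu) {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  tags <- c("s", "p", "m", "d", "e")
  labels <- character(0L); pb <- NULL; pf <- NULL
  interp_at <- function(branch, frac) {
    centers <- t(vapply(branch$lumen, `[[`, numeric(3L), "center"))
    s <- c(0, cumsum(row_norms(diff(centers))))
    st <- frac * s[length(s)]
    apply(centers, 2L, function(cc) stats::approx(s, cc, xout = st)$y)
  }
  for (bn in names(bl$branches)) {
    if (!bn %in% names(fu$branches)) next
    for (k in seq_along(fracs)) {
      labels <- c(labels, paste0(tags[k], bn))
      pb <- rbind(pb, interp_at(bl$branches[[bn]], fracs[k]))
      pf <- rbind(pf, interp_at(fu$branches[[bn]], fracs[k]))
    }
  }
  marker_set(labels, pb, pf)
}

#' The ten-case artificial baseline/follow-up validation suite
#'
#' Builds the ten artificial pairs with known plaque-thickness differences:
#' lumen radius decreases of 0.50 mm at plaque lengths 4/6/2 mm (cases
#' 1-3), lumen decreases of 0.25 and 1.00 mm and an increase of 0.50 mm at
#' L = 4 mm (cases 4-6), three plaques at the proximal/middle/distal RCA
#' (case 7), one plaque on each of RCA/LAD/LCx (case 8), a wall-only
#' increase of 0.50 mm (case 9, positive remodeling), and simultaneous
#' +0.50 mm lumen and wall edits with zero net thickness change (case 10).
#' Each follow-up additionally receives a rigid pose perturbation and
#' radial contour jitter.
#'
#' @param base_config a [tree_config()] for the host anatomy.
#' @param seed integer seed controlling poses and jitter.
#' @param noise_sd radial contour jitter sd (mm) for the follow-ups.
#' @param outdir optional directory; when given, each case's trees and
#'   ground truth are written as JSON.
#' @return list of 10 cases, each `list(no, label, created, specs, bl, fu,
#'   truth)`.
#' @export
table2_suite <- function(base_config = tree_config(), seed = 1L,
                         noise_sd = 0.05, outdir = NULL) {
  bl <- generate_tree(base_config)
  mid <- function(bn) {
    b <- Filter(function(x) x$name == bn, base_config$branches)[[1L]]
    b$length / 2
  }
  len <- function(bn) {
    b <- Filter(function(x) x$name == bn, base_config$branches)[[1L]]
    b$length
  }
  cases <- list(
    list(no = 1L, label = "L=4 dRl=-0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_lumen = -0.50))),
    list(no = 2L, label = "L=6 dRl=-0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 6, dR_lumen = -0.50))),
    list(no = 3L, label = "L=2 dRl=-0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 2, dR_lumen = -0.50))),
    list(no = 4L, label = "L=4 dRl=-0.25",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_lumen = -0.25))),
    list(no = 5L, label = "L=4 dRl=-1.00",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_lumen = -1.00))),
    list(no = 6L, label = "L=4 dRl=+0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_lumen = +0.50))),
    list(no = 7L, label = "3 plaques prox/mid/dist RCA",
         specs = list(
           plaque_spec("RCA", 0.25 * len("RCA"), 4, dR_lumen = -0.50),
           plaque_spec("RCA", 0.50 * len("RCA"), 4, dR_lumen = -0.50),
           plaque_spec("RCA", 0.75 * len("RCA"), 4, dR_lumen = -0.50))),
    list(no = 8L, label = "plaque on RCA/LAD/LCx",
         specs = list(
           plaque_spec("RCA", mid("RCA"), 4, dR_lumen = -0.50),
           plaque_spec("LAD", mid("LAD"), 4, dR_lumen = -0.50),
           plaque_spec("LCx", mid("LCx"), 4, dR_lumen = -0.50))),
    list(no = 9L, label = "L=4 dRv=+0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_wall = +0.50))),
    list(no = 10L, label = "L=4 dRl=+0.50 dRv=+0.50",
         specs = list(plaque_spec("RCA", mid("RCA"), 4, dR_lumen = +0.50,
                                  dR_wall = +0.50))))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (ci in seq_along(cases)) {
    ed <- apply_plaque(bl, cases[[ci]]$specs)
    ang <- stats::runif(1L, 5, 15)
    ax <- stats::rnorm(3L); ax <- unit(ax)
    tv <- stats::runif(3L, -1, 1); tv <- tv / max(1e-9, vec_norm(tv)) *
      stats::runif(1L, 2, 10)
    cases[[ci]]$bl <- bl
    cases[[ci]]$fu <- make_followup(ed$tree, rotation = ang, axis = ax,
                                    translation = tv, noise_sd = noise_sd,
                                    seed = seed + 1000L * ci)
    cases[[ci]]$truth <- ed$truth
    cases[[ci]]$created <- vapply(ed$truth, `[[`, numeric(1L), "created")
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_tree(cases[[ci]]$bl,
                 file.path(outdir, sprintf("case%02d_bl.json", ci)))
      write_tree(cases[[ci]]$fu,
                 file.path(outdir, sprintf("case%02d_fu.json", ci)))
      gt <- lapply(ed$truth, function(r)
        list(branch = r$branch, s_range = r$window,
             created_diff_mm = r$created))
      jsonlite::write_json(gt, file.path(outdir,
                                         sprintf("case%02d_truth.json", ci)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  cases
}
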