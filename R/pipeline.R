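# End-to-end orchestration: centerlines -> rigid CPD -> correspondence ->
# follow-up surface fitting -> coarse-mesh mapping -> baseline fitting ->
# thickness differencing, classification, statistics and export.

#' Pipeline configuration
#'
#' @param spacing centerline resample spacing (mm).
#' @param cpd list of CPD controls: `w` (outlier weight), `scale`
#'   (estimate scale), `tol`, `max_iter`.
#' @param subdivision list of fitting controls: `levels`, `step`,
#'   `smooth_weight`, `smooth_normal`, `max_iter`, `force_tol`, `K`
#'   (angular samples); see [fit_to_contours()].
#' @param threshold classification cut-off (mm).
#' @param seed integer seed recorded in reports.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = 0.5,
                            cpd = list(w = 0.1, scale = FALSE, tol = 1e-8,
                                       max_iter = 150L),
                            subdivision = list(levels = 2L, step = 0.5,
                                               smooth_weight = 0.2,
                                               smooth_normal = 0.25,
                                               max_iter = 80L,
                                               force_tol = 0.02, K = 48L),
                            threshold = 0.5, seed = 1L) {
  def <- formals(pipeline_config)
  cpd <- utils::modifyList(eval(def$cpd), cpd)
  subdivision <- utils::modifyList(eval(def$subdivision), subdivision)
  stopifnot(spacing > 0, threshold > 0, cpd$w >= 0, cpd$w < 1,
            subdivision$levels >= 1L)
  structure(list(spacing = spacing, cpd = cpd, subdivision = subdivision,
                 threshold = threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' YAML or JSON, selected by file extension.
#'
#' @param path config file path.
#' @export
read_config <- function(path) {
  lst <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::read_yaml(path) else
      jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, lst)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.stage <- function(name, quiet, ...) {
  if (!quiet) message(sprintf("[plaquediff] %-22s %s", name,
                              paste0(..., collapse = "")))
}

# Arclength stations of arbitrary points projected onto a polyline
# (nearest-segment orthogonal projection, clamped).
project_stations <- function(points, line_pts, line_s) {
  n <- nrow(line_pts)
  a <- line_pts[-n, , drop = FALSE]
  e <- line_pts[-1L, , drop = FALSE] - a
  el2 <- rowSums(e * e)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    w <- sweep(a, 2L, points[i, ], `-`)
    t <- pmin(1, pmax(0, -rowSums(w * e) / el2))
    d2 <- rowSums((w + t * e)^2)
    j <- which.min(d2)
    out[i] <- line_s[j] + t[j] * (line_s[j + 1L] - line_s[j])
  }
  out
}

#' Run the full baseline/follow-up comparison pipeline
#'
#' Executes, per branch: centerline extraction and 0.5 mm resampling for
#' both trees; pooled rigid CPD registering the follow-up centerline
#' cloud onto the baseline; one-to-one correspondence resolution;
#' follow-up coarse-mesh construction and lumen-then-wall subdivision
#' fitting; coarse-mesh mapping into baseline coordinates; baseline
#' fitting from the mapped coarse mesh; per-vertex thickness on all four
#' surfaces; differencing, classification and statistics. Deterministic
#' given inputs and config.
#'
#' @param bl,fu baseline and follow-up [coronary_tree()] objects or paths
#'   to JSON contour files.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for report JSON and colored
#'   meshes.
#' @param quiet suppress stage log messages.
#' @return An object of class `plaquediff_report`: `transform`,
#'   `registration` (iterations, sigma2, correspondence counts), `diff`
#'   (classified per-vertex [compute_diff()] field), `thickness_bl`,
#'   `thickness_fu`, `surfaces`, `fit_residuals`, `stats` (overall and
#'   per-branch), `config`.
#' @export
run_compare <- function(bl, fu, config = pipeline_config(), outdir = NULL,
                        quiet = FALSE) {
  t0 <- Sys.time()
  if (is.character(bl)) bl <- read_tree(bl)
  if (is.character(fu)) fu <- read_tree(fu)
  sub <- config$subdivision

  .stage("centerlines", quiet, "extract + resample at ",
         config$spacing, " mm")
  cl_bl <- lapply(bl$branches, function(b)
    resample_centerline(extract_centerline(b, bl$ostium), config$spacing))
  cl_fu <- lapply(fu$branches, function(b)
    resample_centerline(extract_centerline(b, fu$ostium), config$spacing))
  common <- intersect(names(cl_bl), names(cl_fu))
  if (length(common) == 0L) stop("no branch names shared between trees")
  Y <- do.call(rbind, lapply(cl_bl[common], `[[`, "points"))
  X <- do.call(rbind, lapply(cl_fu[common], `[[`, "points"))
  fu_offsets <- c(0L, cumsum(vapply(cl_fu[common],
                                    function(c) nrow(c$points), 0L)))

  .stage("rigid CPD", quiet, nrow(X), " FU -> ", nrow(Y), " BL points, w=",
         config$cpd$w)
  reg <- rigid_cpd(X, Y, w = config$cpd$w, scale = config$cpd$scale,
                   max_iter = config$cpd$max_iter, tol = config$cpd$tol)
  TX <- apply_transform(reg$transform, X)
  cmap <- resolve_correspondence(reg$P, TX, Y)
  .stage("correspondence", quiet, nrow(cmap$pairs), " pairs, ",
         length(cmap$unmatched_fu), " unmatched FU, ",
         length(cmap$unmatched_bl), " unmatched BL")

  th_bl <- list(); th_fu <- list(); surfaces <- list(); fitres <- list()
  for (bi in seq_along(common)) {
    bn <- common[bi]
    .stage(paste0("fit ", bn), quiet)
    lum_fu <- contour_stack(fu$branches[[bn]], "lumen", K = sub$K)
    wal_fu <- contour_stack(fu$branches[[bn]], "wall", K = sub$K)
    lum_bl <- contour_stack(bl$branches[[bn]], "lumen", K = sub$K)
    wal_bl <- contour_stack(bl$branches[[bn]], "wall", K = sub$K)
    r0 <- 0.5 * min(lum_fu$radii)
    coarse_fu <- build_coarse_mesh(cl_fu[[bn]], r0)
    fit_fu <- fit_lumen_then_wall(coarse_fu, lum_fu, wal_fu,
                                  levels = sub$levels, step = sub$step,
                                  smooth_weight = sub$smooth_weight,
                                  max_iter = sub$max_iter,
                                  smooth_normal = sub$smooth_normal,
                                  force_tol = sub$force_tol)
    coarse_bl <- map_coarse_mesh(coarse_fu, cmap, reg$transform,
                                 index_offset = fu_offsets[bi])
    # restate ring stations in baseline arclength terms
    ring_ctr <- t(apply(coarse_bl$rings, 1L, colMeans))
    coarse_bl$stations <- project_stations(ring_ctr, cl_bl[[bn]]$points,
                                           cl_bl[[bn]]$arclengths)
    fit_bl <- fit_lumen_then_wall(coarse_bl, lum_bl, wal_bl,
                                  levels = sub$levels, step = sub$step,
                                  smooth_weight = sub$smooth_weight,
                                  max_iter = sub$max_iter,
                                  smooth_normal = sub$smooth_normal,
                                  force_tol = sub$force_tol)
    th_bl[[bn]] <- compute_thickness(fit_bl$lumen, fit_bl$wall)
    th_fu[[bn]] <- compute_thickness(fit_fu$lumen, fit_fu$wall)
    surfaces[[bn]] <- list(bl = fit_bl, fu = fit_fu)
    fitres[[bn]] <- c(fu_lumen = fit_fu$lumen$fit$rms,
                      fu_wall = fit_fu$wall$fit$rms,
                      bl_lumen = fit_bl$lumen$fit$rms,
                      bl_wall = fit_bl$wall$fit$rms)
    .stage(paste0("fit ", bn), quiet, "RMS residuals (mm): ",
           paste(sprintf("%.3f", fitres[[bn]]), collapse = " "))
  }
  thickness_bl <- do.call(rbind, unname(th_bl))
  thickness_fu <- do.call(rbind, unname(th_fu))
  class(thickness_bl) <- class(thickness_fu) <-
    c("thickness_field", "data.frame")
  dif <- classify_changes(compute_diff(thickness_bl, thickness_fu),
                          config$threshold)
  stats_all <- region_stats(dif)
  stats_branch <- lapply(common, function(bn) region_stats(dif, branch = bn))
  names(stats_branch) <- common
  .stage("difference", quiet,
         sprintf("mean %.3f sd %.3f mm over %d vertices",
                 stats_all$mean, stats_all$sd, stats_all$n))
  report <- structure(
    list(transform = reg$transform,
         registration = list(iterations = reg$iterations,
                             sigma2 = reg$sigma2,
                             converged = reg$converged,
                             n_pairs = nrow(cmap$pairs),
                             n_unmatched_fu = length(cmap$unmatched_fu),
                             n_unmatched_bl = length(cmap$unmatched_bl)),
         diff = dif, thickness_bl = thickness_bl,
         thickness_fu = thickness_fu, surfaces = surfaces,
         fit_residuals = fitres,
         stats = list(overall = stats_all, per_branch = stats_branch),
         config = config,
         runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "plaquediff_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.plaquediff_report <- function(x, ...) {
  cat("plaquediff comparison report\n")
  cat(sprintf("  registration: %d pairs, sigma2 %.4g, %d EM iterations\n",
              x$registration$n_pairs, x$registration$sigma2,
              x$registration$iterations))
  s <- x$stats$overall
  cat(sprintf("  DIF_thickness: mean %+.3f sd %.3f min %+.3f max %+.3f mm (n=%d)\n",
              s$mean, s$sd, s$min, s$max, s$n))
  cat(sprintf("  classified: %.1f%% increase, %.1f%% decrease (threshold %.2f mm)\n",
              s$pct_increase, s$pct_decrease, x$config$threshold))
  invisible(x)
}

# Serialise a report: report.json + colored meshes per branch.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    transform = list(rotation = as.numeric(t(report$transform$R)),
                     scale = report$transform$s,
                     translation = report$transform$t),
    registration = report$registration,
    stats = report$stats,
    fit_residuals_mm = report$fit_residuals,
    threshold_mm = report$config$threshold,
    runtime_s = report$runtime_s)
  jsonlite::write_json(js, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  for (bn in names(report$surfaces)) {
    surf <- report$surfaces[[bn]]$bl$lumen
    fld <- report$diff[report$diff$branch == bn, ]
    export_colored(surf, fld, file.path(outdir, paste0(bn, "_diff.ply")),
                   mode = "continuous")
    export_colored(surf, fld, file.path(outdir,
                                        paste0(bn, "_diff_thresholded.vtk")),
                   mode = "thresholded", threshold = report$config$threshold)
  }
  invisible(outdir)
}

#' Run the ten-case artificial validation suite
#'
#' Generates the artificial baseline/follow-up suite ([table2_suite()]),
#' runs [run_compare()] on every case and summarises the calculated mean
#' thickness difference over each created plaque region against its known
#' value.
#'
#' @param config a [pipeline_config()]; its `seed` drives the suite's
#'   pose perturbations and contour jitter.
#' @param base_config [tree_config()] for the host anatomy.
#' @param noise_sd follow-up contour jitter sd (mm).
#' @param outdir optional directory for `summary.csv` and per-case reports.
#' @param quiet suppress stage logs.
#' @return list with `summary` (data.frame: case, region, created_mm,
#'   mean_mm, sd_mm, n) and `reports` (per-case `plaquediff_report`s) and
#'   `cases`.
#' @export
run_table2 <- function(config = pipeline_config(),
                       base_config = tree_config(),
                       noise_sd = 0.05, outdir = NULL, quiet = TRUE) {
  cases <- table2_suite(base_config, seed = config$seed,
                        noise_sd = noise_sd)
  rows <- list(); reports <- vector("list", length(cases))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    if (!quiet) message(sprintf("[plaquediff] case %02d: %s", cs$no,
                                cs$label))
    rep_i <- run_compare(cs$bl, cs$fu, config, quiet = TRUE)
    reports[[ci]] <- rep_i
    for (ri in seq_along(cs$truth)) {
      rec <- cs$truth[[ri]]
      st <- region_stats(rep_i$diff, branch = rec$branch,
                         window = rec$interior)
      rows[[length(rows) + 1L]] <- data.frame(
        case = cs$no, region = ri, branch = rec$branch,
        created_mm = rec$created, mean_mm = st$mean, sd_mm = st$sd,
        n = st$n)
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    for (ci in seq_along(reports))
      write_report(reports[[ci]],
                   file.path(outdir, sprintf("case%02d", ci)))
  }
  list(summary = summary, reports = reports, cases = cases)
}

#' Registration-only marker evaluation
#'
#' Registers the follow-up centerline cloud onto the baseline and reports
#' per-marker Euclidean distances between baseline markers and registered
#' follow-up markers, grouped by anatomical position label.
#'
#' @param bl,fu trees or JSON paths.
#' @param markers a [marker_set()] or path to a markers JSON file.
#' @param config a [pipeline_config()].
#' @return list with `transform`, `per_marker`, `mean`, `sd`, and
#'   `by_group` (mean distance per position label).
#' @export
run_marker_eval <- function(bl, fu, markers, config = pipeline_config()) {
  if (is.character(bl)) bl <- read_tree(bl)
  if (is.character(fu)) fu <- read_tree(fu)
  if (is.character(markers)) markers <- read_markers(markers)
  cl_bl <- lapply(bl$branches, function(b)
    resample_centerline(extract_centerline(b, bl$ostium), config$spacing))
  cl_fu <- lapply(fu$branches, function(b)
    resample_centerline(extract_centerline(b, fu$ostium), config$spacing))
  common <- intersect(names(cl_bl), names(cl_fu))
  Y <- do.call(rbind, lapply(cl_bl[common], `[[`, "points"))
  X <- do.call(rbind, lapply(cl_fu[common], `[[`, "points"))
  reg <- rigid_cpd(X, Y, w = config$cpd$w, scale = config$cpd$scale,
                   max_iter = config$cpd$max_iter, tol = config$cpd$tol)
  ev <- evaluate_markers(markers, reg$transform)
  grp <- substr(ev$per_marker$label, 1L, 1L)
  list(transform = reg$transform, per_marker = ev$per_marker,
       mean = ev$mean, sd = ev$sd,
       by_group = tapply(ev$per_marker$distance_mm, grp, mean))
}
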