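# Rigid coherent point drift (CPD) registration of follow-up centerline
# points onto baseline centerline points, and construction of one-to-one
# correspondences with per-point translation vectors.

#' Rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @param scale positive scalar (1 unless scale estimation was enabled).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  R <- as.matrix(rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("rotation must be orthonormal with det +1")
  if (scale <= 0) stop("scale must be positive")
  structure(list(R = R, s = scale, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of points.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points)))
    return(drop(transform$s * transform$R %*% points) + transform$t)
  sweep(points %*% t(transform$R) * transform$s, 2L, transform$t, `+`)
}

#' Rigid coherent point drift registration
#'
#' Registers the moving point set `X` (follow-up) onto the fixed set `Y`
#' (baseline) with the rigid CPD model: `Y` is treated as data drawn from
#' an isotropic Gaussian mixture centered on the transformed `X` plus a
#' uniform outlier component of weight `w`. The EM iteration updates the
#' posterior (E-step) and solves rotation via SVD of the weighted
#' cross-covariance with determinant correction, translation from weighted
#' means, and the shared variance `sigma2` (M-step), until the relative
#' change of the objective falls below `tol` or `max_iter` is reached.
#'
#' @param X moving points, M x 3 (follow-up centerline, mm).
#' @param Y fixed points, N x 3 (baseline centerline, mm).
#' @param w outlier weight in `[0, 1)`; default 0.1 tolerates branch
#'   segments present in only one acquisition.
#' @param scale estimate a global scale factor (default `FALSE`: same
#'   patient, mm units).
#' @param max_iter,tol EM stopping controls.
#' @return list with `transform` ([rigid_transform()]), `P` (M x N
#'   posterior matrix; column k holds the component posteriors of baseline
#'   point k and sums to at most 1), `sigma2`, `iterations`, `converged`,
#'   and `objective` (per-iteration negative log-likelihood trace).
#' @export
rigid_cpd <- function(X, Y, w = 0.1, scale = FALSE, max_iter = 150L,
                      tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  M <- nrow(X); N <- nrow(Y)
  if (M < 3L || N < 3L) stop("need at least 3 points in each set")
  if (w < 0 || w >= 1) stop("w must be in [0, 1)")
  D <- 3
  # pooled variance initialisation over all cross pairs
  sigma2 <- (M * sum(Y^2) + N * sum(X^2) -
               2 * sum(colSums(X) * colSums(Y))) / (M * N * D)
  R <- diag(3); s <- 1; tvec <- rep(0, 3)
  TX <- X
  obj <- numeric(0L)
  prev <- Inf; converged <- FALSE; it <- 0L
  Y2 <- rowSums(Y^2)
  for (it in seq_len(max_iter)) {
    # E-step: D2[i, k] = ||y_k - T(x_i)||^2
    D2 <- outer(rowSums(TX^2), Y2, `+`) - 2 * TX %*% t(Y)
    G <- exp(-D2 / (2 * sigma2))
    cden <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- pmax(colSums(G) + cden, 1e-300)
    P <- sweep(G, 2L, den, `/`)
    Np <- sum(P)
    # true mixture negative log-likelihood at the current parameters
    obj <- c(obj, -sum(log(den)) + N * (D / 2) * log(2 * pi * sigma2) -
               N * log((1 - w) / M))
    # M-step
    Pt1 <- colSums(P)        # length N
    P1 <- rowSums(P)         # length M
    mu_x <- colSums(P1 * X) / Np
    mu_y <- colSums(Pt1 * Y) / Np
    Xh <- sweep(X, 2L, mu_x)
    Yh <- sweep(Y, 2L, mu_y)
    A <- t(Xh) %*% (P %*% Yh)   # D x D cross-covariance (moving x fixed)
    sv <- svd(t(A))
    C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    R <- sv$u %*% C %*% t(sv$v)
    if (scale) {
      s <- sum(diag(t(A) %*% t(R))) / sum(P1 * rowSums(Xh^2))
    } else s <- 1
    tvec <- mu_y - s * drop(R %*% mu_x)
    TX <- sweep(X %*% t(R) * s, 2L, tvec, `+`)
    D2n <- outer(rowSums(TX^2), Y2, `+`) - 2 * TX %*% t(Y)
    sigma2 <- max(sum(P * D2n) / (Np * D), 1e-12)
    cur <- obj[it]
    if (is.finite(prev) && abs(prev - cur) < tol * abs(prev) + 1e-15) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!converged && it >= max_iter)
    warning("rigid CPD did not converge within ", max_iter, " iterations")
  # final posterior at the converged transform
  D2 <- outer(rowSums(TX^2), Y2, `+`) - 2 * TX %*% t(Y)
  G <- exp(-D2 / (2 * sigma2))
  den <- pmax(colSums(G) + (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N,
              1e-300)
  P <- sweep(G, 2L, den, `/`)
  list(transform = rigid_transform(R, tvec, s), P = P, sigma2 = sigma2,
       iterations = it, converged = converged, objective = obj)
}

#' Resolve the CPD posterior to a one-to-one correspondence
#'
#' CPD yields a many-to-one relation (several moving points may favour the
#' same fixed point). Each moving (follow-up) point `i` is provisionally
#' assigned to its maximum-posterior baseline point; for every baseline
#' point that attracted more than one, the Euclidean-closest transformed
#' follow-up point is kept (ties break to the lower follow-up index) and
#' the rest become unmatched. Each kept pair stores the residual
#' translation vector `T_vec = y_k - x_i'` of the transformed point.
#'
#' @param P M x N posterior from [rigid_cpd()].
#' @param X_transformed M x 3 transformed follow-up points.
#' @param Y N x 3 baseline points.
#' @return An object of class `correspondence_map`: `pairs` (data.frame
#'   with `bl`, `fu`, `T.x/T.y/T.z`), `unmatched_bl`, `unmatched_fu`.
#' @export
resolve_correspondence <- function(P, X_transformed, Y) {
  if (is.null(dim(P)) || nrow(P) == 0L || ncol(P) == 0L)
    stop("empty posterior")
  M <- nrow(P); N <- ncol(P)
  stopifnot(nrow(X_transformed) == M, nrow(Y) == N)
  best_k <- max.col(P, ties.method = "first")
  keep_fu <- integer(0L); keep_bl <- integer(0L)
  for (k in unique(best_k)) {
    cand <- which(best_k == k)
    if (length(cand) > 1L) {
      d <- row_norms(sweep(X_transformed[cand, , drop = FALSE], 2L, Y[k, ]))
      cand <- cand[which.min(d)]  # which.min takes the first on ties
    }
    keep_fu <- c(keep_fu, cand)
    keep_bl <- c(keep_bl, k)
  }
  ord <- order(keep_bl)
  keep_bl <- keep_bl[ord]; keep_fu <- keep_fu[ord]
  Tv <- Y[keep_bl, , drop = FALSE] - X_transformed[keep_fu, , drop = FALSE]
  structure(list(
    pairs = data.frame(bl = keep_bl, fu = keep_fu,
                       T.x = Tv[, 1L], T.y = Tv[, 2L], T.z = Tv[, 3L]),
    unmatched_bl = setdiff(seq_len(N), keep_bl),
    unmatched_fu = setdiff(seq_len(M), keep_fu)),
    class = "correspondence_map")
}

#' Evaluate registration accuracy on marker pairs
#'
#' Per marker, the Euclidean distance between the baseline marker and the
#' rigidly registered follow-up marker.
#'
#' @param markers a [marker_set()].
#' @param transform the follow-up-to-baseline [rigid_transform()].
#' @return list with `per_marker` (data.frame label, distance_mm) and
#'   `mean`, `sd` (mm).
#' @export
evaluate_markers <- function(markers, transform) {
  if (nrow(markers) < 1L) stop("no markers")
  pb <- as.matrix(markers[, c("bl.x", "bl.y", "bl.z")])
  pf <- as.matrix(markers[, c("fu.x", "fu.y", "fu.z")])
  d <- row_norms(pb - apply_transform(transform, pf))
  list(per_marker = data.frame(label = markers$label, distance_mm = d),
       mean = mean(d), sd = stats::sd(d))
}
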