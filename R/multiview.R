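# Multi-view geometry: epipolar filtering of correspondences and DLT
# triangulation into the world frame.

camera_matrix <- function(intr, extr) {
  intrinsics_matrix(intr) %*% cbind(extr$R, extr$t)
}

#' Fundamental matrix between two calibrated views
#'
#' Derived from the projection matrices (not estimated):
#' `F = [e2]_x P2 pinv(P1)` with `e2` the epipole of camera 1's center in
#' view 2.
#'
#' @param intr [intrinsics()].
#' @param extr1,extr2 [extrinsics()] of the two views.
#' @return 3 x 3 fundamental matrix (view-1 points to view-2 lines).
#' @export
fundamental_from_cameras <- function(intr, extr1, extr2) {
  P1 <- camera_matrix(intr, extr1)
  P2 <- camera_matrix(intr, extr2)
  C1 <- c(camera_center(extr1), 1)
  e2 <- drop(P2 %*% C1)
  ex <- rbind(c(0, -e2[3], e2[2]), c(e2[3], 0, -e2[1]), c(-e2[2], e2[1], 0))
  s <- svd(P1)
  pinv <- s$v %*% diag(1 / s$d) %*% t(s$u)
  ex %*% P2 %*% pinv
}

point_line_dist <- function(pts, lines) {
  abs(rowSums(cbind(pts, 1) * lines)) / sqrt(lines[, 1]^2 + lines[, 2]^2)
}

# Symmetric epipolar distance of correspondences (max of the two
# point-to-epipolar-line distances).
epipolar_distance <- function(F, uv1, uv2) {
  l2 <- cbind(uv1, 1) %*% t(F)
  l1 <- cbind(uv2, 1) %*% F
  pmax(point_line_dist(uv2, l2), point_line_dist(uv1, l1))
}

eight_point_F <- function(uv1, uv2) {
  n1 <- normalize_points(uv1); n2 <- normalize_points(uv2)
  a <- n1$p; b <- n2$p
  A <- cbind(b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1],
             b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2],
             a[, 1], a[, 2], 1)
  f <- svd(A, nu = 0, nv = 9)$v[, 9]
  F0 <- matrix(f, 3, 3, byrow = TRUE)
  s <- svd(F0)
  F0 <- s$u %*% diag(c(s$d[1:2], 0)) %*% t(s$v)   # enforce rank 2
  t(n2$T) %*% F0 %*% n1$T
}

#' Epipolar filtering of correspondences
#'
#' Keeps matches whose symmetric epipolar distance is at most `threshold`
#' pixels. With calibrated cameras the fundamental matrix is derived from
#' the calibration; without, it is RANSAC-estimated from the matches
#' themselves (normalized 8-point minimal samples).
#'
#' @param matches Data.frame with columns `view_a`, `view_b`, `ua`, `va`,
#'   `ub`, `vb` (all rows must share one view pair when `cameras` is `NULL`).
#' @param cameras `NULL`, or a list with `intr` and `views` (list of
#'   [extrinsics()]) as returned by [calibrate_ransac()] / [rig_poses()].
#' @param threshold Inlier threshold in pixels (default 1).
#' @param iterations,seed RANSAC settings for the uncalibrated path.
#' @return The inlier subset of `matches`.
#' @export
epipolar_filter <- function(matches, cameras = NULL, threshold = 1,
                            iterations = 2000, seed = 42) {
  if (!is.null(cameras)) {
    keep <- logical(nrow(matches))
    for (pair in unique(paste(matches$view_a, matches$view_b))) {
      sel <- paste(matches$view_a, matches$view_b) == pair
      a <- matches$view_a[sel][1]; b <- matches$view_b[sel][1]
      F <- fundamental_from_cameras(cameras$intr, cameras$views[[a]],
                                    cameras$views[[b]])
      d <- epipolar_distance(F, cbind(matches$ua[sel], matches$va[sel]),
                             cbind(matches$ub[sel], matches$vb[sel]))
      keep[sel] <- d <= threshold
    }
    return(matches[keep, , drop = FALSE])
  }
  if (nrow(matches) < 8) stop("insufficient matches (need >= 8 for RANSAC)")
  uv1 <- cbind(matches$ua, matches$va); uv2 <- cbind(matches$ub, matches$vb)
  with_seed(seed, {
    best <- NULL; best_count <- -1
    for (it in seq_len(iterations)) {
      s <- sample.int(nrow(matches), 8)
      F <- tryCatch(eight_point_F(uv1[s, ], uv2[s, ]),
                    error = function(e) NULL)
      if (is.null(F)) next
      d <- epipolar_distance(F, uv1, uv2)
      cnt <- sum(d <= threshold)
      if (cnt > best_count) { best_count <- cnt; best <- F }
    }
    d <- epipolar_distance(best, uv1, uv2)
    matches[d <= threshold, , drop = FALSE]
  })
}

#' Triangulate one correspondence by DLT
#'
#' Homogeneous linear (DLT) triangulation from two calibrated views, with a
#' reprojection-error report and a cheirality flag.
#'
#' @param match One-row data.frame (`view_a`, `view_b`, `ua`, `va`, `ub`,
#'   `vb`) or a list with those fields.
#' @param cameras List with `intr` and `views` as in [epipolar_filter()].
#' @return List: `point` (world 3-vector), `reproj_error` (mean px over the
#'   two views), `in_front` (logical).
#' @export
triangulate <- function(match, cameras) {
  a <- match$view_a; b <- match$view_b
  if (a == b) stop("views must differ")
  e1 <- cameras$views[[a]]; e2 <- cameras$views[[b]]
  if (sum((camera_center(e1) - camera_center(e2))^2) < 1e-16)
    stop("degenerate baseline")
  P1 <- camera_matrix(cameras$intr, e1)
  P2 <- camera_matrix(cameras$intr, e2)
  A <- rbind(match$ua * P1[3, ] - P1[1, ],
             match$va * P1[3, ] - P1[2, ],
             match$ub * P2[3, ] - P2[1, ],
             match$vb * P2[3, ] - P2[2, ])
  Xh <- svd(A, nu = 0, nv = 4)$v[, 4]
  if (abs(Xh[4]) < 1e-14) stop("degenerate baseline")
  X <- Xh[1:3] / Xh[4]
  z1 <- drop(e1$R %*% X + e1$t)[3]
  z2 <- drop(e2$R %*% X + e2$t)[3]
  p1 <- project(X, cameras$intr, e1)
  p2 <- project(X, cameras$intr, e2)
  err <- (sqrt(sum((p1 - c(match$ua, match$va))^2)) +
            sqrt(sum((p2 - c(match$ub, match$vb))^2))) / 2
  list(point = X, reproj_error = err, in_front = z1 > 0 && z2 > 0)
}

# Vectorized inhomogeneous DLT over many matches of one view pair
# (solves A[,1:3] X = -A[,4] in least squares via closed-form 3x3 normals).
triangulate_pair <- function(uv1, uv2, P1, P2) {
  n <- nrow(uv1)
  rows <- list(
    outer(uv1[, 1], P1[3, ]) - matrix(P1[1, ], n, 4, byrow = TRUE),
    outer(uv1[, 2], P1[3, ]) - matrix(P1[2, ], n, 4, byrow = TRUE),
    outer(uv2[, 1], P2[3, ]) - matrix(P2[1, ], n, 4, byrow = TRUE),
    outer(uv2[, 2], P2[3, ]) - matrix(P2[2, ], n, 4, byrow = TRUE))
  M <- matrix(0, n, 9); rhs <- matrix(0, n, 3)
  for (r in rows) {
    a <- r[, 1:3, drop = FALSE]; d <- r[, 4]
    M <- M + cbind(a[, 1] * a[, 1], a[, 1] * a[, 2], a[, 1] * a[, 3],
                   a[, 2] * a[, 1], a[, 2] * a[, 2], a[, 2] * a[, 3],
                   a[, 3] * a[, 1], a[, 3] * a[, 2], a[, 3] * a[, 3])
    rhs <- rhs - a * d
  }
  # closed-form symmetric 3x3 solve per row (cofactor expansion)
  a11 <- M[, 1]; a12 <- M[, 2]; a13 <- M[, 3]
  a22 <- M[, 5]; a23 <- M[, 6]; a33 <- M[, 9]
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  i11 <- (a22 * a33 - a23^2) / det
  i12 <- (a13 * a23 - a12 * a33) / det
  i13 <- (a12 * a23 - a13 * a22) / det
  i22 <- (a11 * a33 - a13^2) / det
  i23 <- (a13 * a12 - a11 * a23) / det
  i33 <- (a11 * a22 - a12^2) / det
  cbind(i11 * rhs[, 1] + i12 * rhs[, 2] + i13 * rhs[, 3],
        i12 * rhs[, 1] + i22 * rhs[, 2] + i23 * rhs[, 3],
        i13 * rhs[, 1] + i23 * rhs[, 2] + i33 * rhs[, 3])
}

#' Build a point cloud from masked multi-view correspondences
#'
#' Runs the correspondence provider, restricts matches to the foreground
#' masks of both views, filters them by the calibration-derived epipolar
#' constraint, triangulates, rejects points behind either camera or with
#' reprojection error above the threshold, samples colors from the first
#' view's image, and merges duplicates on a voxel grid.
#'
#' @param images List of h x w x 3 arrays (0..255).
#' @param masks List of logical h x w foreground masks.
#' @param cameras List with `intr` and `views`.
#' @param detector `function(images, masks, cameras)` returning a
#'   correspondence data.frame (see [ground_truth_detector()]).
#' @param epipolar_px Epipolar inlier threshold (px).
#' @param reproj_px Reprojection-error threshold (px).
#' @param merge_voxel_cm Duplicate-merge voxel size (cm); 0 disables merging.
#' @return [point_cloud()] with colors.
#' @export
build_cloud <- function(images, masks, cameras, detector,
                        epipolar_px = 1, reproj_px = 1,
                        merge_voxel_cm = 0.1) {
  stopifnot(length(images) == length(masks),
            length(images) == length(cameras$views))
  if (!any(vapply(masks, any, logical(1)))) stop("no plant pixels")
  matches <- detector(images, masks, cameras)
  if (is.null(matches) || nrow(matches) == 0) stop("no correspondences")
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  in_mask <- function(view, u, v) {
    px <- pmin(pmax(round(u), 0), w - 1)
    py <- pmin(pmax(round(v), 0), h - 1)
    vapply(seq_along(u), function(i) masks[[view[i]]][py[i] + 1, px[i] + 1],
           logical(1))
  }
  keep <- in_mask(matches$view_a, matches$ua, matches$va) &
    in_mask(matches$view_b, matches$ub, matches$vb)
  matches <- matches[keep, , drop = FALSE]
  if (nrow(matches) == 0) stop("no plant pixels among correspondences")
  matches <- epipolar_filter(matches, cameras, threshold = epipolar_px)
  pts <- NULL; cols <- NULL
  for (pair in unique(paste(matches$view_a, matches$view_b))) {
    sel <- paste(matches$view_a, matches$view_b) == pair
    a <- matches$view_a[sel][1]; b <- matches$view_b[sel][1]
    P1 <- camera_matrix(cameras$intr, cameras$views[[a]])
    P2 <- camera_matrix(cameras$intr, cameras$views[[b]])
    uv1 <- cbind(matches$ua[sel], matches$va[sel])
    uv2 <- cbind(matches$ub[sel], matches$vb[sel])
    X <- triangulate_pair(uv1, uv2, P1, P2)
    e1 <- cameras$views[[a]]; e2 <- cameras$views[[b]]
    z1 <- X %*% e1$R[3, ] + e1$t[3]
    z2 <- X %*% e2$R[3, ] + e2$t[3]
    ok <- is.finite(rowSums(X)) & z1 > 0 & z2 > 0
    if (!any(ok)) next
    pr1 <- project(X[ok, , drop = FALSE], cameras$intr, e1)
    pr2 <- project(X[ok, , drop = FALSE], cameras$intr, e2)
    re <- (sqrt(rowSums((pr1 - uv1[ok, , drop = FALSE])^2)) +
             sqrt(rowSums((pr2 - uv2[ok, , drop = FALSE])^2))) / 2
    ok2 <- re <= reproj_px
    Xk <- X[ok, , drop = FALSE][ok2, , drop = FALSE]
    if (!nrow(Xk)) next
    uu <- uv1[ok, 1][ok2]; vv <- uv1[ok, 2][ok2]
    px <- pmin(pmax(round(uu), 0), w - 1); py <- pmin(pmax(round(vv), 0), h - 1)
    img <- images[[a]]
    cc <- cbind(img[cbind(py + 1, px + 1, 1)],
                img[cbind(py + 1, px + 1, 2)],
                img[cbind(py + 1, px + 1, 3)])
    pts <- rbind(pts, Xk); cols <- rbind(cols, cc)
  }
  if (is.null(pts) || nrow(pts) == 0) stop("triangulation produced no points")
  merge_voxels(point_cloud(pts, colors = pmin(pmax(cols, 0), 255)),
               merge_voxel_cm)
}
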