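# Planar calibration: Zhang-style initialization from homographies, a RANSAC
# loop over point correspondences per view, and joint Levenberg-Marquardt
# refinement of intrinsics, radial distortion k1 and all poses.

normalize_points <- function(p) {
  cen <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, cen)^2))
  s <- sqrt(2) / mean(d)
  T <- rbind(c(s, 0, -s * cen[1]), c(0, s, -s * cen[2]), c(0, 0, 1))
  list(p = sweep(p, 2, cen) * s, T = T)
}

# Direct linear transform homography: world (x, y) -> image (u, v),
# with Hartley normalization of both point sets.
homography_dlt <- function(world, image) {
  stopifnot(nrow(world) >= 4)
  nw <- normalize_points(world); ni <- normalize_points(image)
  w <- nw$p; m <- ni$p
  A <- matrix(0, 2 * nrow(w), 9)
  for (i in seq_len(nrow(w))) {
    X <- c(w[i, 1], w[i, 2], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, m[i, 1] * X)
    A[2 * i, ] <- c(0, 0, 0, -X, m[i, 2] * X)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(ni$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% nw$T
  H / H[3, 3]
}

apply_homography <- function(H, world) {
  Xh <- cbind(world, 1) %*% t(H)
  cbind(Xh[, 1] / Xh[, 3], Xh[, 2] / Xh[, 3])
}

# RANSAC homography over correspondences; transfer-error inlier test.
ransac_homography <- function(world, image, threshold = 2, iterations = 1000,
                              seed = 42) {
  n <- nrow(world)
  if (n < 4) stop("need at least 4 correspondences")
  with_seed(seed, {
    best <- NULL; best_count <- -1
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 4)
      H <- tryCatch(homography_dlt(world[s, , drop = FALSE],
                                   image[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H) || any(!is.finite(H))) next
      pred <- apply_homography(H, world)
      err <- sqrt(rowSums((pred - image)^2))
      cnt <- sum(err <= threshold)
      if (cnt > best_count) { best_count <- cnt; best <- H }
    }
    if (is.null(best)) stop("homography estimation failed")
    err <- sqrt(rowSums((apply_homography(best, world) - image)^2))
    inliers <- err <= threshold
    if (sum(inliers) >= 4)
      best <- homography_dlt(world[inliers, , drop = FALSE],
                             image[inliers, , drop = FALSE])
    err <- sqrt(rowSums((apply_homography(best, world) - image)^2))
    list(H = best, inliers = err <= threshold)
  })
}

# Closed-form intrinsics from >= 3 planar homographies (Zhang's method);
# the skew estimate is computed and discarded (the camera model has none).
zhang_intrinsics <- function(Hs) {
  vij <- function(H, i, j) {
    h1 <- H[, i]; h2 <- H[, j]
    c(h1[1] * h2[1], h1[1] * h2[2] + h1[2] * h2[1], h1[2] * h2[2],
      h1[3] * h2[1] + h1[1] * h2[3], h1[3] * h2[2] + h1[2] * h2[3],
      h1[3] * h2[3])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  b <- svd(V, nu = 0)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  v0 <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  fx <- sqrt(lam / B11)
  fy <- sqrt(lam * B11 / (B11 * B22 - B12^2))
  skew <- -B12 * fx^2 * fy / lam
  u0 <- skew * v0 / fy - B13 * fx^2 / lam
  if (!all(is.finite(c(fx, fy, u0, v0))) || fx <= 0 || fy <= 0)
    stop("intrinsics initialization failed")
  intrinsics(fx, fy, u0, v0)
}

pose_from_homography <- function(H, intr) {
  A <- intrinsics_matrix(intr)
  Ai <- solve(A)
  h1 <- Ai %*% H[, 1]; h2 <- Ai %*% H[, 2]; h3 <- Ai %*% H[, 3]
  lam <- 1 / sqrt(sum(h1^2))
  if (h3[3] * lam < 0) lam <- -lam   # camera must face the mat
  r1 <- lam * h1; r2 <- lam * h2
  r3 <- cross3(drop(r1), drop(r2))
  R <- cbind(r1, r2, r3)
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  extrinsics(R, lam * h3)
}

rodrigues_vec <- function(R) {
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  ax * ang
}

rodrigues_mat <- function(w) {
  ang <- sqrt(sum(w^2))
  if (ang < 1e-12) return(diag(3))
  k <- w / ang
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' RANSAC settings for planar calibration
#'
#' @param iterations RANSAC iterations per view (default 1000).
#' @param threshold Inlier reprojection/transfer error threshold in pixels
#'   (default 2).
#' @param seed RNG seed making the estimate bit-reproducible (default 42).
#' @export
ransac_config <- function(iterations = 1000, threshold = 2, seed = 42) {
  list(iterations = iterations, threshold = threshold, seed = seed)
}

#' RANSAC-robust planar camera calibration
#'
#' Calibrates from per-view correspondences between the dot calibration mat
#' (world points on z = 0, cm) and their detected image positions. Pipeline:
#' per-view RANSAC homography (transfer-error inlier test), Zhang-style
#' closed-form intrinsics from the inlier homographies, per-view pose
#' recovery, then joint Levenberg-Marquardt refinement of
#' `fx, fy, u0, v0, k1` and all poses minimizing inlier reprojection error
#' under the radial distortion model.
#'
#' @param correspondences List (one entry per view) of data.frames with
#'   columns `id`, `u`, `v` as returned by [detect_target_points()].
#' @param target [calibration_target()] supplying world coordinates per id.
#' @param config [ransac_config()].
#' @return Object of class `"camera_calibration"`: `intr` ([intrinsics()]),
#'   `views` (list of [extrinsics()]), `k1`, `inliers` (list of logical
#'   masks, one per correspondence row per view), `mean_reproj_error` (px,
#'   over inliers), `view_used` (logical).
#' @export
calibrate_ransac <- function(correspondences, target,
                             config = ransac_config()) {
  if (length(correspondences) < 3) stop("insufficient views (need >= 3)")
  wp <- target$points
  per_view <- lapply(correspondences, function(df) {
    m <- match(df$id, wp$id)
    if (any(is.na(m))) stop("correspondence ids not on the target")
    list(world = cbind(wp$x_cm[m], wp$y_cm[m]), image = cbind(df$u, df$v))
  })
  hr <- vector("list", length(per_view))
  usable <- logical(length(per_view))
  for (v in seq_along(per_view)) {
    pv <- per_view[[v]]
    if (nrow(pv$world) < 4) next
    hr[[v]] <- tryCatch(
      ransac_homography(pv$world, pv$image, config$threshold,
                        config$iterations, config$seed + v),
      error = function(e) NULL)
    usable[v] <- !is.null(hr[[v]]) && sum(hr[[v]]$inliers) >= 4
  }
  if (sum(usable) < 3) stop("insufficient views (need >= 3 usable)")
  intr0 <- zhang_intrinsics(lapply(hr[usable], `[[`, "H"))
  poses0 <- lapply(which(usable), function(v)
    pose_from_homography(hr[[v]]$H, intr0))

  used <- which(usable)
  inlier0 <- lapply(hr[used], `[[`, "inliers")
  # parameter vector: fx fy u0 v0 k1 then per-view (rodrigues, t)
  pack <- function(intr, k1, poses) {
    c(intr$fx, intr$fy, intr$u0, intr$v0, k1,
      unlist(lapply(poses, function(e) c(rodrigues_vec(e$R), e$t))))
  }
  unpack <- function(p) {
    intr <- intrinsics(p[1], p[2], p[3], p[4])
    k1 <- p[5]
    poses <- lapply(seq_along(used), function(i) {
      off <- 5 + (i - 1) * 6
      extrinsics(rodrigues_mat(p[off + 1:3]), p[off + 4:6])
    })
    list(intr = intr, k1 = k1, poses = poses)
  }
  residual_fun <- function(p, masks) {
    pr <- unpack(p)
    unlist(lapply(seq_along(used), function(i) {
      pv <- per_view[[used[i]]]
      sel <- masks[[i]]
      w3 <- cbind(pv$world[sel, , drop = FALSE], 0)
      pred <- project(w3, pr$intr, pr$poses[[i]])
      pred <- radial_correct(pred, pr$intr, pr$k1)
      as.numeric(pred - pv$image[sel, , drop = FALSE])
    }))
  }
  classify <- function(pr) {
    lapply(seq_along(used), function(i) {
      pv <- per_view[[used[i]]]
      pred <- radial_correct(project(cbind(pv$world, 0), pr$intr,
                                     pr$poses[[i]]), pr$intr, pr$k1)
      sqrt(rowSums((pred - pv$image)^2)) <= config$threshold
    })
  }
  # two LM passes: points displaced by strong radial distortion are often
  # homography-stage outliers, so reclassify under the refined distortion
  # model and refit
  p0 <- pack(intr0, 0, poses0)
  masks <- inlier0
  for (pass in 1:2) {
    fit <- minpack.lm::nls.lm(p0, fn = residual_fun, masks = masks,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100, ptol = 1e-10, ftol = 1e-10))
    pr <- unpack(fit$par)
    new_masks <- classify(pr)
    if (identical(new_masks, masks)) break
    masks <- new_masks
    p0 <- fit$par
  }
  # final inlier classification on all correspondences of the used views
  inliers <- vector("list", length(per_view))
  err_sum <- 0; err_n <- 0
  for (i in seq_along(used)) {
    pv <- per_view[[used[i]]]
    pred <- radial_correct(project(cbind(pv$world, 0), pr$intr,
                                   pr$poses[[i]]), pr$intr, pr$k1)
    err <- sqrt(rowSums((pred - pv$image)^2))
    inliers[[used[i]]] <- err <= config$threshold
    err_sum <- err_sum + sum(err[err <= config$threshold])
    err_n <- err_n + sum(err <= config$threshold)
  }
  total <- sum(vapply(per_view[used], function(pv) nrow(pv$image), 0))
  if (err_n / total < 0.5) stop("calibration unreliable: inlier ratio < 50%")
  structure(list(intr = pr$intr, views = pr$poses, k1 = pr$k1,
                 inliers = inliers, mean_reproj_error = err_sum / err_n,
                 view_used = usable),
            class = "camera_calibration")
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf(
    "camera calibration: fx=%.2f fy=%.2f u0=%.2f v0=%.2f k1=%.5f\n",
    x$intr$fx, x$intr$fy, x$intr$u0, x$intr$v0, x$k1))
  cat(sprintf("  %d views, mean inlier reprojection error %.4f px\n",
              length(x$views), x$mean_reproj_error))
  invisible(x)
}

#' Detect and identify calibration-mat dots in an image
#'
#' Thresholds dark blobs, labels connected components and takes their
#' centroids (sub-pixel). The four size-coded fiducial markers are recognized
#' as the four largest blobs and ranked by area; the homography they define
#' transfers every nominal dot position into the image, and each is matched
#' to the nearest detected centroid.
#'
#' @param image h x w x 3 array (0..255) showing the rendered mat.
#' @param target [calibration_target()].
#' @param dark_threshold Gray level below which a pixel belongs to a blob.
#' @param match_tol_px Maximum distance between a transferred nominal dot and
#'   its matched centroid.
#' @return data.frame with columns `id`, `u`, `v` (>= 4 rows), sorted by id.
#' @export
detect_target_points <- function(image, target, dark_threshold = 128,
                                 match_tol_px = 4) {
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  bin <- gray < dark_threshold
  if (!any(bin)) stop("target not found: no dark blobs")
  lab <- EBImage::bwlabel(bin * 1)
  nlab <- max(lab)
  if (nlab < 8) stop("target not found: too few blobs")
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  cu <- tapply(idx[, 2] - 1, labv, mean)   # u = col - 1
  cv <- tapply(idx[, 1] - 1, labv, mean)   # v = row - 1
  area <- tabulate(labv, nbins = nlab)
  ord <- order(area, decreasing = TRUE)
  fid_lab <- ord[1:4]
  fw <- cbind(target$fiducials$x_cm, target$fiducials$y_cm)
  fi <- cbind(cu[fid_lab], cv[fid_lab])
  dot_lab <- setdiff(seq_len(nlab), fid_lab)
  dot_lab <- dot_lab[area[dot_lab] >= 3]
  if (!length(dot_lab)) stop("target not found: no dot blobs")
  du <- cu[dot_lab]; dv <- cv[dot_lab]
  # corner assignment: sort both squares into convex (angular) order, then
  # try every cyclic shift and both directions, keeping the homography that
  # transfers the most nominal dots onto detected centroids
  ang_order <- function(p) order(atan2(p[, 2] - mean(p[, 2]),
                                       p[, 1] - mean(p[, 1])))
  fw <- fw[ang_order(fw), , drop = FALSE]
  fi <- fi[ang_order(fi), , drop = FALSE]
  world_pts <- cbind(target$points$x_cm, target$points$y_cm)
  # the fiducial-only homography is scored as-is: refitting on matched dots
  # before the permutation is fixed would let the 24-degree dot pattern's
  # near-90-degree alias absorb its offset and tie the true assignment
  best <- NULL; best_matches <- -1; best_dist <- Inf
  for (shift in 0:3) for (dir in c(1, -1)) {
    perm <- if (dir == 1) ((seq_len(4) - 1 + shift) %% 4) + 1
            else ((4 - seq_len(4) + 1 + shift) %% 4) + 1
    H0 <- tryCatch(homography_dlt(fw, fi[perm, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(H0)) next
    nom <- apply_homography(H0, world_pts)
    d2 <- vapply(seq_len(nrow(nom)), function(i)
      min((du - nom[i, 1])^2 + (dv - nom[i, 2])^2), numeric(1))
    hit <- d2 <= match_tol_px^2
    cnt <- sum(hit); dist <- sum(sqrt(d2[hit]))
    if (cnt > best_matches ||
        (cnt == best_matches && dist < best_dist)) {
      best_matches <- cnt; best <- H0; best_dist <- dist
    }
  }
  if (is.null(best) || best_matches < 4) stop("target not found")
  nominal <- apply_homography(best, world_pts)
  res <- lapply(seq_len(nrow(nominal)), function(i) {
    d2 <- (du - nominal[i, 1])^2 + (dv - nominal[i, 2])^2
    j <- which.min(d2)
    if (d2[j] <= match_tol_px^2)
      data.frame(id = target$points$id[i], u = unname(du[j]),
                 v = unname(dv[j]), blob = dot_lab[j], d2 = d2[j])
    else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) < 4) stop("target not found")
  # a blob may serve at most one dot: keep the nearest assignment per blob
  out <- out[order(out$d2), , drop = FALSE]
  out <- out[!duplicated(out$blob), , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("id", "u", "v")]
}
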