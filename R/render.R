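# Minimal z-buffered point-splat renderer for the synthetic turntable rig.
# Sufficient for silhouette, correspondence and calibration fixtures; it is
# not a ray tracer (no shading or self-shadowing).

splat_offsets <- function(radius_px) {
  r <- ceiling(radius_px)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius_px^2, ]
}

# Rasterize projected points into an h x w x 3 image (0..255) with z-buffer.
# uv: N x 2 subpixel coords, depth: camera z, col: N x 3.
rasterize <- function(uv, depth, col, width, height, background,
                      splat_px = 1.5) {
  img <- array(rep(background, each = height * width), c(height, width, 3))
  zbuf <- matrix(Inf, height, width)
  owner <- matrix(NA_integer_, height, width)
  off <- splat_offsets(splat_px)
  px <- round(uv[, 1]); py <- round(uv[, 2])
  ord <- order(depth, decreasing = TRUE)  # far first; near overwrites
  for (k in seq_len(nrow(off))) {
    x <- px[ord] + off$dx[k]; y <- py[ord] + off$dy[k]
    ok <- x >= 0 & x < width & y >= 0 & y < height
    idx <- (y[ok]) + 1 + height * (x[ok])   # linear index into h x w
    src <- ord[ok]
    beat <- depth[src] <= zbuf[idx]          # do not overwrite nearer splats
    idx <- idx[beat]; src <- src[beat]
    zbuf[idx] <- depth[src]
    owner[idx] <- src
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- col[src, ch]
      img[, , ch] <- plane
    }
  }
  list(image = img, zbuf = zbuf, owner = owner)
}

project_view <- function(points, intr, extr, k1 = 0) {
  Xc <- points %*% t(extr$R) + matrix(extr$t, nrow(points), 3, byrow = TRUE)
  uv <- cbind(intr$fx * Xc[, 1] / Xc[, 3] + intr$u0,
              intr$fy * Xc[, 2] / Xc[, 3] + intr$v0)
  if (k1 != 0) uv <- radial_correct(uv, intr, k1)
  list(uv = uv, depth = Xc[, 3])
}

#' Render calibrated turntable views of a plant cloud
#'
#' Point-splat renders the cloud on a blue background in every rig view and
#' records, for each pair of consecutive same-ring views, the ground-truth
#' correspondences of a subset of "dot" samples visible in both (visibility
#' via the z-buffer). These correspondences play the role of an interest-point
#' detector/matcher for reconstruction tests; optional Gaussian pixel noise
#' emulates localisation error.
#'
#' @param cloud [point_cloud()] with colors.
#' @param rig [turntable_rig()].
#' @param intr [intrinsics()] with `width`/`height` attached.
#' @param n_dots Number of cloud samples used as matchable dots.
#' @param pixel_noise_sd Gaussian noise (px) added to correspondence
#'   coordinates (not to the rendered images).
#' @param background Background RGB (default a chroma blue).
#' @param splat_px Splat radius in pixels.
#' @param seed Seed for dot choice and pixel noise.
#' @return Object of class `"render_set"`: `images` (list of h x w x 3
#'   arrays), `silhouettes` (list of logical h x w ground-truth masks),
#'   `poses`, `intr`, `correspondences` (data.frame view_a, view_b, point_id,
#'   ua, va, ub, vb, score), `dot_ids`, `dot_xyz`.
#' @export
render_views <- function(cloud, rig, intr, n_dots = 1200,
                         pixel_noise_sd = 0, background = c(30, 40, 220),
                         splat_px = 1.5, seed = 1) {
  if (nrow(cloud$positions) == 0) stop("empty scene")
  if (is.null(intr$width) || is.null(intr$height))
    stop("intrinsics need an attached image size")
  poses <- rig_poses(rig)
  P <- cloud$positions
  col <- cloud$colors
  if (is.null(col)) col <- matrix(0, nrow(P), 3)
  with_seed(seed, {
    dot_ids <- sort(sample.int(nrow(P), min(n_dots, nrow(P))))
    images <- vector("list", length(poses))
    sils <- vector("list", length(poses))
    uvs <- vector("list", length(poses))
    visible <- matrix(FALSE, length(dot_ids), length(poses))
    for (v in seq_along(poses)) {
      pr <- project_view(P, intr, poses[[v]])
      ras <- rasterize(pr$uv, pr$depth, col, intr$width, intr$height,
                       background, splat_px)
      images[[v]] <- ras$image
      sils[[v]] <- is.finite(ras$zbuf)
      uvs[[v]] <- pr$uv[dot_ids, , drop = FALSE]
      # dot visible if it is (nearly) the closest sample on its pixel
      px <- pmin(pmax(round(pr$uv[dot_ids, 1]), 0), intr$width - 1)
      py <- pmin(pmax(round(pr$uv[dot_ids, 2]), 0), intr$height - 1)
      zb <- ras$zbuf[py + 1 + intr$height * px]
      visible[, v] <- pr$depth[dot_ids] <= zb + 0.75
    }
    ring <- attr(poses, "ring"); stp <- attr(poses, "stop")
    pairs <- do.call(rbind, lapply(seq_along(poses), function(v) {
      nxt <- which(ring == ring[v] & stp == (stp[v] %% rig$stops) + 1)
      if (length(nxt) == 1 && rig$stops > 1) c(v, nxt) else NULL
    }))
    cor_list <- lapply(seq_len(NROW(pairs)), function(pi) {
      a <- pairs[pi, 1]; b <- pairs[pi, 2]
      both <- which(visible[, a] & visible[, b])
      if (!length(both)) return(NULL)
      data.frame(view_a = a, view_b = b, point_id = dot_ids[both],
                 ua = uvs[[a]][both, 1], va = uvs[[a]][both, 2],
                 ub = uvs[[b]][both, 1], vb = uvs[[b]][both, 2],
                 score = 1)
    })
    corres <- do.call(rbind, cor_list)
    if (pixel_noise_sd > 0 && !is.null(corres)) {
      nn <- nrow(corres)
      corres$ua <- corres$ua + stats::rnorm(nn, 0, pixel_noise_sd)
      corres$va <- corres$va + stats::rnorm(nn, 0, pixel_noise_sd)
      corres$ub <- corres$ub + stats::rnorm(nn, 0, pixel_noise_sd)
      corres$vb <- corres$vb + stats::rnorm(nn, 0, pixel_noise_sd)
    }
    structure(list(images = images, silhouettes = sils, poses = poses,
                   intr = intr, correspondences = corres,
                   dot_ids = dot_ids, dot_xyz = P[dot_ids, , drop = FALSE]),
              class = "render_set")
  })
}

#' Ground-truth correspondence detector for a render set
#'
#' Returns a detector function usable by [build_cloud()]: it ignores the
#' images and hands back the render set's recorded dot correspondences, the
#' injectable stand-in for a SURF-style interest-point matcher.
#'
#' @param render_set A [render_views()] result.
#' @return `function(images, masks, cameras)` returning the correspondence
#'   data.frame.
#' @export
ground_truth_detector <- function(render_set) {
  force(render_set)
  function(images, masks, cameras) render_set$correspondences
}

#' Render calibration-mat views
#'
#' Renders the dot calibration target (black dots and size-coded fiducial
#' markers on a white mat, all on the plane z = 0) in the given poses,
#' applying the radial distortion `k1` to every projected pixel. Dots are
#' rendered by densely sampling each disc in world space so their image is a
#' true perspective ellipse.
#'
#' @param target [calibration_target()].
#' @param poses List of [extrinsics()].
#' @param intr [intrinsics()] with width/height.
#' @param k1 Radial distortion coefficient applied to the rendering.
#' @param omit_ids Optional dot ids left out (occlusion fixtures).
#' @return List of h x w x 3 images (0..255).
#' @export
render_target_views <- function(target, poses, intr, k1 = 0,
                                omit_ids = NULL) {
  if (is.null(intr$width) || is.null(intr$height))
    stop("intrinsics need an attached image size")
  disc <- function(cx, cy, r, step = 0.06) {
    g <- expand.grid(x = seq(-r, r, by = step), y = seq(-r, r, by = step))
    g <- g[g$x^2 + g$y^2 <= r^2, ]
    cbind(cx + g$x, cy + g$y, 0)
  }
  pts <- target$points
  if (!is.null(omit_ids)) pts <- pts[!(pts$id %in% omit_ids), , drop = FALSE]
  dots <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    disc(pts$x_cm[i], pts$y_cm[i], target$dot_radius_cm)))
  fids <- do.call(rbind, lapply(seq_len(nrow(target$fiducials)), function(i)
    disc(target$fiducials$x_cm[i], target$fiducials$y_cm[i],
         target$fiducials$radius_cm[i], step = 0.1)))
  world <- rbind(dots, fids)
  lapply(poses, function(extr) {
    pr <- project_view(world, intr, extr, k1 = k1)
    img <- array(255, c(intr$height, intr$width, 3))
    px <- round(pr$uv[, 1]); py <- round(pr$uv[, 2])
    ok <- px >= 0 & px < intr$width & py >= 0 & py < intr$height
    idx <- py[ok] + 1 + intr$height * px[ok]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- 0
      img[, , ch] <- plane
    }
    img
  })
}
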