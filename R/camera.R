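#' Camera intrinsics
#'
#' Internal parameter matrix of the classical pinhole model: focal lengths
#' `fx`, `fy` in pixel units and the principal point `(u0, v0)` in pixels.
#'
#' @param fx,fy Focal lengths in pixel units; must be positive.
#' @param u0,v0 Principal point in pixel coordinates (origin at the top-left
#'   corner, x right, y down, pixel centers at integer coordinates).
#' @param width,height Optional attached image size in pixels; when given, the
#'   principal point must lie inside the image.
#' @return An object of class `"intrinsics"`.
#' @examples
#' K <- intrinsics(500, 500, 320, 240)
#' intrinsics_matrix(K)
#' @export
intrinsics <- function(fx, fy, u0, v0, width = NULL, height = NULL) {
  stopifnot(is.numeric(fx), is.numeric(fy), fx > 0, fy > 0,
            is.finite(u0), is.finite(v0))
  if (!is.null(width) && !is.null(height)) {
    if (u0 < 0 || u0 > width - 1 || v0 < 0 || v0 > height - 1)
      stop("principal point outside image bounds")
  }
  structure(list(fx = fx, fy = fy, u0 = u0, v0 = v0,
                 width = width, height = height),
            class = "intrinsics")
}

#' @rdname intrinsics
#' @param intr An `"intrinsics"` object.
#' @export
intrinsics_matrix <- function(intr) {
  matrix(c(intr$fx, 0, intr$u0,
           0, intr$fy, intr$v0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' @export
print.intrinsics <- function(x, ...) {
  cat(sprintf("intrinsics: fx=%.3f fy=%.3f u0=%.3f v0=%.3f\n",
              x$fx, x$fy, x$u0, x$v0))
  invisible(x)
}

#' Camera extrinsics (world -> camera rigid transform)
#'
#' @param R 3x3 rotation matrix mapping world to camera coordinates. Checked
#'   for orthonormality (`t(R) %*% R = I` and `det(R) = +1`, both to 1e-9).
#' @param t Length-3 translation so that `X_cam = R %*% X_world + t`.
#' @return An object of class `"extrinsics"`.
#' @export
extrinsics <- function(R, t) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    stop("R is not a proper rotation (det != +1)")
  structure(list(R = R, t = t), class = "extrinsics")
}

#' @rdname extrinsics
#' @param extr An `"extrinsics"` object.
#' @return `camera_center()`: the camera center in world coordinates.
#' @export
camera_center <- function(extr) {
  drop(-crossprod(extr$R, extr$t))
}

#' Lens distortion model
#'
#' Coefficients of the classical decomposition of geometric lens distortion
#' into radial (`k1`, `k2`), centrifugal/tangential (`p1`, `p2`) and thin-prism
#' (`s1`, `s2`) components, all acting on normalized image coordinates. Only
#' `k1` participates in the correction path ([radial_correct()]); the full
#' forward model ([distort_forward()]) exists for simulation.
#'
#' @param k1,k2 Radial coefficients.
#' @param p1,p2 Tangential (centrifugal) coefficients.
#' @param s1,s2 Thin-prism coefficients.
#' @return An object of class `"distortion_model"`.
#' @export
distortion_model <- function(k1 = 0, k2 = 0, p1 = 0, p2 = 0, s1 = 0, s2 = 0) {
  co <- c(k1 = k1, k2 = k2, p1 = p1, p2 = p2, s1 = s1, s2 = s2)
  stopifnot(all(is.finite(co)))
  structure(as.list(co), class = "distortion_model")
}

#' Project a world point through a calibrated camera
#'
#' Perspective projection `s*(u,v,1)' = K [R t] (x,y,z,1)'` with the
#' homogeneous scale eliminated.
#'
#' @param point Numeric length-3 world point, or an N x 3 matrix of points.
#' @param intr [intrinsics()].
#' @param extr [extrinsics()].
#' @return Length-2 pixel `(u, v)` or an N x 2 matrix.
#' @export
project <- function(point, intr, extr) {
  P <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  Xc <- P %*% t(extr$R) + matrix(extr$t, nrow(P), 3, byrow = TRUE)
  if (any(abs(Xc[, 3]) < 1e-12))
    stop("point at infinity in image (camera-frame z = 0)")
  uv <- cbind(intr$fx * Xc[, 1] / Xc[, 3] + intr$u0,
              intr$fy * Xc[, 2] / Xc[, 3] + intr$v0)
  if (is.matrix(point)) uv else drop(uv)
}

#' Forward lens distortion on normalized coordinates
#'
#' Applies the full displacement model (radial + centrifugal + thin-prism) to
#' ideal normalized coordinates:
#' \deqn{\delta_x = k_1 x r^2 + k_2 x r^4 + p_1(3x^2+y^2) + 2 p_2 x y + s_1 r^2}
#' \deqn{\delta_y = k_1 y r^2 + k_2 y r^4 + p_2(3x^2+y^2) + 2 p_1 x y + s_2 r^2}
#' with \eqn{r^2 = x^2 + y^2}; the returned point is \eqn{(x+\delta_x, y+\delta_y)}.
#' With all coefficients zero this is the identity.
#'
#' @param xy Length-2 normalized point or N x 2 matrix.
#' @param model [distortion_model()].
#' @return Displaced normalized point(s), same shape as `xy`.
#' @export
distort_forward <- function(xy, model) {
  P <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  if (!all(is.finite(P))) stop("non-finite normalized coordinates")
  x <- P[, 1]; y <- P[, 2]
  r2 <- x^2 + y^2
  dx <- (model$k1 * x * r2 + model$k2 * x * r2^2) +
    (model$p1 * (3 * x^2 + y^2) + 2 * model$p2 * x * y) +
    model$s1 * r2
  dy <- (model$k1 * y * r2 + model$k2 * y * r2^2) +
    (model$p2 * (3 * x^2 + y^2) + 2 * model$p1 * x * y) +
    model$s2 * r2
  out <- cbind(x + dx, y + dy)
  if (is.matrix(xy)) out else drop(out)
}

#' Radial distortion of pixel coordinates
#'
#' The radial-only correction model used by the calibration path:
#' \deqn{u_d = u + k_1 (u - u_0) r^2, \quad v_d = v + k_1 (v - v_0) r^2}
#' where \eqn{r^2 = x_n^2 + y_n^2} is computed from the idealized normalized
#' coordinates \eqn{x_n = (u-u_0)/f_x}, \eqn{y_n = (v-v_0)/f_y}.
#'
#' @param uv Length-2 ideal pixel or N x 2 matrix.
#' @param intr [intrinsics()].
#' @param k1 Radial distortion coefficient.
#' @return Distorted pixel(s) `(ud, vd)`, same shape as `uv`.
#' @seealso [radial_undistort()] for the inverse map.
#' @export
radial_correct <- function(uv, intr, k1) {
  P <- if (is.matrix(uv)) uv else matrix(uv, ncol = 2)
  xn <- (P[, 1] - intr$u0) / intr$fx
  yn <- (P[, 2] - intr$v0) / intr$fy
  r2 <- xn^2 + yn^2
  out <- cbind(P[, 1] + k1 * (P[, 1] - intr$u0) * r2,
               P[, 2] + k1 * (P[, 2] - intr$v0) * r2)
  if (is.matrix(uv)) out else drop(out)
}

#' Invert the radial distortion by fixed-point iteration
#'
#' Given a distorted pixel `(ud, vd)`, recovers the ideal pixel `(u, v)` such
#' that `radial_correct((u, v)) = (ud, vd)`. Fixed-point iteration with a
#' 1e-8 normalized-unit stopping tolerance; accurate to well under 1e-6 px
#' for moderate distortion (|k1| <= 0.2 over the usual field of view).
#'
#' @param uv_d Length-2 distorted pixel or N x 2 matrix.
#' @inheritParams radial_correct
#' @param iterations Maximum fixed-point iterations.
#' @param tol Stopping tolerance in normalized units.
#' @export
radial_undistort <- function(uv_d, intr, k1, iterations = 40, tol = 1e-10) {
  P <- if (is.matrix(uv_d)) uv_d else matrix(uv_d, ncol = 2)
  xd <- (P[, 1] - intr$u0) / intr$fx
  yd <- (P[, 2] - intr$v0) / intr$fy
  x <- xd; y <- yd
  for (i in seq_len(iterations)) {
    r2 <- x^2 + y^2
    x_new <- xd / (1 + k1 * r2)
    y_new <- yd / (1 + k1 * r2)
    if (max(abs(x_new - x), abs(y_new - y)) < tol) { x <- x_new; y <- y_new; break }
    x <- x_new; y <- y_new
  }
  out <- cbind(intr$u0 + x * intr$fx, intr$v0 + y * intr$fy)
  if (is.matrix(uv_d)) out else drop(out)
}

#' Radial dot calibration target
#'
#' A planar calibration mat of 15 groups x 4 dots (60 dots) arranged on a
#' large radial circle on the plane z = 0, world units cm. The exact mat
#' geometry is a synthetic stand-in: groups sit at a 24 degree angular pitch
#' and each group's four dots lie at four radii spanning two concentric rings.
#' Four oversized corner fiducial markers (outside the 60 pattern dots) make
#' dot identification in an image a simple homography transfer; they are not
#' part of the 60-point pattern.
#'
#' @param groups Number of radial groups (default 15).
#' @param per_group Dots per group (default 4).
#' @param radii Radii (cm) of the dots within each group, innermost first.
#' @param dot_radius_cm Rendered dot radius in cm.
#' @return Object of class `"calibration_target"` with `$points`
#'   (data.frame: id, group, x_cm, y_cm) and `$fiducials` (data.frame:
#'   id, x_cm, y_cm, radius_cm, size-ranked).
#' @export
calibration_target <- function(groups = 15, per_group = 4,
                               radii = c(9, 12, 15, 18),
                               dot_radius_cm = 0.45) {
  stopifnot(groups >= 1, per_group == length(radii))
  ang <- (seq_len(groups) - 1) * 2 * pi / groups
  pts <- do.call(rbind, lapply(seq_len(groups), function(g) {
    data.frame(id = (g - 1) * per_group + seq_len(per_group),
               group = g,
               x_cm = radii * cos(ang[g]),
               y_cm = radii * sin(ang[g]))
  }))
  rmax <- max(radii) + 4
  # an irregular quadrilateral: a symmetric square would leave the mat's
  # mirror/rotation symmetries unbroken and dot identification ambiguous
  fid <- data.frame(id = paste0("F", 1:4),
                    x_cm = c(1.10, -1.00, -1.10, 1.00) * rmax,
                    y_cm = c(1.00, 1.05, -0.90, -1.15) * rmax,
                    radius_cm = c(1.9, 1.7, 1.5, 1.3))
  spacing <- min(dist(cbind(pts$x_cm, pts$y_cm)))
  structure(list(points = pts, fiducials = fid,
                 dot_radius_cm = dot_radius_cm,
                 min_spacing_cm = spacing,
                 groups = groups, per_group = per_group, radii = radii),
            class = "calibration_target")
}

#' Write a calibration target's dot layout to CSV
#' @param target [calibration_target()].
#' @param path Output CSV path (columns id, x_cm, y_cm).
#' @export
write_target_csv <- function(target, path) {
  utils::write.csv(target$points[, c("id", "x_cm", "y_cm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Turntable imaging rig
#'
#' The multi-view acquisition geometry: a camera on a vertical rail imaging a
#' plant on a motorized turntable. One full revolution per camera elevation
#' ("ring"); by default 4 rings of 15 stops = 60 views, elevations between 10
#' and 25 degrees, matching the acquisition platform's circular-photography
#' scheme.
#'
#' @param rings Number of camera elevation rings (default 4).
#' @param stops Stops per revolution (default 15; azimuth step 360/stops).
#' @param elevations_deg Elevation angle of each ring in degrees
#'   (default `c(10, 15, 20, 25)`; must lie in \[10, 25\]).
#' @param distance_cm Camera-to-turntable-center distance (default 120 cm).
#' @param look_at Point the optical axis passes through (default
#'   `c(0, 0, 25)`, slightly above the turntable so the plant fills the frame).
#' @return Object of class `"turntable_rig"`.
#' @export
turntable_rig <- function(rings = 4, stops = 15,
                          elevations_deg = c(10, 15, 20, 25),
                          distance_cm = 120, look_at = c(0, 0, 25)) {
  stopifnot(rings >= 1, stops >= 1, length(elevations_deg) == rings)
  if (any(elevations_deg < 10 - 1e-9) || any(elevations_deg > 25 + 1e-9))
    stop("elevations must lie in [10, 25] degrees")
  structure(list(rings = rings, stops = stops,
                 elevations_deg = elevations_deg,
                 distance_cm = distance_cm, look_at = look_at),
            class = "turntable_rig")
}

look_at_extrinsics <- function(center, target, up = c(0, 0, 1)) {
  z <- target - center
  z <- z / sqrt(sum(z^2))
  x <- c(z[2] * up[3] - z[3] * up[2],
         z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  nx <- sqrt(sum(x^2))
  if (nx < 1e-12) stop("optical axis parallel to the up direction")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  # re-orthonormalize against accumulated rounding
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  extrinsics(R, -R %*% center)
}

#' Camera poses of a turntable rig
#'
#' One extrinsic pose per (ring, stop): the camera sits at the ring's
#' elevation and the stop's azimuth at `distance_cm` from the turntable axis,
#' looking at `look_at`. Stops advance azimuth by 360/stops degrees, so
#' consecutive same-ring poses differ by a pure azimuth rotation about the
#' world vertical axis (24 degrees for the default 15-stop rig).
#'
#' @param rig [turntable_rig()].
#' @return List of [extrinsics()] of length `rings * stops`, ring-major, with
#'   attributes `ring` and `stop` (integer vectors).
#' @export
rig_poses <- function(rig) {
  n <- rig$rings * rig$stops
  poses <- vector("list", n)
  ring_id <- integer(n); stop_id <- integer(n)
  k <- 0
  for (ri in seq_len(rig$rings)) {
    el <- rig$elevations_deg[ri] * pi / 180
    for (si in seq_len(rig$stops)) {
      az <- (si - 1) * 2 * pi / rig$stops
      center <- rig$look_at + rig$distance_cm *
        c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
      k <- k + 1
      poses[[k]] <- look_at_extrinsics(center, rig$look_at)
      ring_id[k] <- ri; stop_id[k] <- si
    }
  }
  attr(poses, "ring") <- ring_id
  attr(poses, "stop") <- stop_id
  poses
}

#' Angle of the relative rotation between two poses
#' @param e1,e2 [extrinsics()] objects.
#' @return Rotation angle in degrees of `R2 %*% t(R1)`.
#' @export
relative_rotation_angle <- function(e1, e2) {
  Rrel <- e2$R %*% t(e1$R)
  acos(min(1, max(-1, (sum(diag(Rrel)) - 1) / 2))) * 180 / pi
}
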