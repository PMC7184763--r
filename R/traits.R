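#' Minimum-area enclosing rectangle of 2D points
#'
#' Rotating-calipers construction: the minimum-area rectangle has one side
#' collinear with an edge of the convex hull, so the optimum is found by
#' sweeping the hull's edge directions. Plant length is the longer rectangle
#' side, plant width the shorter.
#'
#' @param points N x 2 numeric matrix; at least 3 non-collinear points.
#' @return List with `length`, `width` (length >= width), `angle` (radians,
#'   direction of the length side in \[0, pi)), `corners` (4 x 2 matrix,
#'   counter-clockwise) and `area`.
#' @export
min_area_rectangle <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 3) stop("degenerate projection: need >= 3 points")
  hull <- points[grDevices::chull(points), , drop = FALSE]
  if (nrow(hull) < 3) stop("degenerate projection: points are collinear")
  edges <- hull[c(2:nrow(hull), 1), ] - hull
  elen <- sqrt(rowSums(edges^2))
  keep <- elen > 1e-12
  if (!any(keep)) stop("degenerate projection: points are collinear")
  theta <- atan2(edges[keep, 2], edges[keep, 1]) %% pi
  best <- NULL
  for (th in unique(theta)) {
    ct <- cos(th); st <- sin(th)
    u <- hull %*% c(ct, st)      # along edge direction
    v <- hull %*% c(-st, ct)     # perpendicular
    du <- max(u) - min(u); dv <- max(v) - min(v)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      best <- list(area = area, th = th, u0 = min(u), u1 = max(u),
                   v0 = min(v), v1 = max(v), du = du, dv = dv)
    }
  }
  ct <- cos(best$th); st <- sin(best$th)
  uv <- rbind(c(best$u0, best$v0), c(best$u1, best$v0),
              c(best$u1, best$v1), c(best$u0, best$v1))
  corners <- uv %*% rbind(c(ct, st), c(-st, ct))
  if (best$du >= best$dv) {
    len <- best$du; wid <- best$dv; angle <- best$th
  } else {
    len <- best$dv; wid <- best$du; angle <- (best$th + pi / 2) %% pi
  }
  list(length = len, width = wid, angle = angle,
       corners = corners, area = best$area)
}

#' Ground reference frame for trait extraction
#'
#' @param vertical_axis Unit 3-vector of the "up" direction (default +z).
#' @param cotyledon_height_cm Height of the cotyledon node above the ground
#'   plane; the zero reference for plant height and canopy height. `NULL`
#'   means estimate it from the cloud ([estimate_cotyledon_height()]).
#' @return Object of class `"ground_frame"`.
#' @export
ground_frame <- function(vertical_axis = c(0, 0, 1),
                         cotyledon_height_cm = NULL) {
  vertical_axis <- as.numeric(vertical_axis)
  stopifnot(abs(sqrt(sum(vertical_axis^2)) - 1) < 1e-9)
  structure(list(vertical_axis = vertical_axis,
                 cotyledon_height_cm = cotyledon_height_cm),
            class = "ground_frame")
}

heights_along_axis <- function(cloud, frame) {
  drop(cloud$positions %*% frame$vertical_axis)
}

#' Estimate the cotyledon-node height from a cloud
#'
#' The plant cloud's lowest foreground points sit at the cotyledon node (the
#' hypocotyl below it is hidden by the pot rim), so the default estimate is
#' the base of the lowest height slice: the 0.1th percentile of the height
#' distribution, which stays within millimetres of the node at usual sampling
#' densities while shrugging off isolated low outliers. A user-supplied
#' override always wins; clouds spanning under 2 cm vertically fall back to
#' the ground height.
#'
#' @param cloud [point_cloud()].
#' @param frame [ground_frame()].
#' @param percentile Height percentile taken as the node (default 0.001).
#' @param override User-supplied height (cm); returned as-is when not `NULL`.
#' @return Height (cm) along the frame's vertical axis.
#' @export
estimate_cotyledon_height <- function(cloud, frame = ground_frame(),
                                      percentile = 0.001, override = NULL) {
  if (!is.null(override)) return(override)
  z <- heights_along_axis(cloud, frame)
  if (diff(range(z)) <= 2) return(min(z))
  unname(stats::quantile(z, percentile))
}

#' Extract the six canopy traits from a point cloud
#'
#' Trait definitions:
#' * plant length / plant width: sides of the minimum circumscribed rectangle
#'   of the cloud's ground-plane projection (length = longer side);
#' * canopy height: vertical distance from the cotyledon node to the highest
#'   point of the plant;
#' * plant height: vertical distance from the cotyledon node to the stem
#'   growing point (apex), located as the highest point within `stem_radius_cm`
#'   of the vertical stem axis (the axis passes through the centroid of the
#'   lowest 10\% of points);
#' * canopy area = plant length x plant width (cm^2);
#' * plant volume = plant length x plant width x canopy height / 1000 (dm^3).
#'
#' @param cloud [point_cloud()] (or a [triangle_mesh()], whose vertices are
#'   used).
#' @param frame [ground_frame()]; a `NULL` cotyledon height is estimated via
#'   [estimate_cotyledon_height()].
#' @param stem_radius_cm Radius of the stem-axis cylinder used to find the
#'   growing point (default 2 cm).
#' @param variety,stage,days Metadata carried into the record.
#' @return Object of class `"trait_record"`: a one-row data.frame with
#'   columns `variety`, `stage`, `days`, `plant_length_cm`, `plant_width_cm`,
#'   `plant_height_cm`, `canopy_height_cm`, `canopy_area_cm2`,
#'   `plant_volume_dm3`, plus attributes `ground_z` and `cotyledon_z`.
#' @export
extract_traits <- function(cloud, frame = ground_frame(),
                           stem_radius_cm = 2,
                           variety = NA_character_, stage = NA_character_,
                           days = NA_real_) {
  if (inherits(cloud, "triangle_mesh"))
    cloud <- point_cloud(cloud$vertices)
  if (nrow(cloud$positions) < 3) stop("degenerate cloud: need >= 3 points")
  z <- heights_along_axis(cloud, frame)
  cot <- frame$cotyledon_height_cm
  if (is.null(cot)) cot <- estimate_cotyledon_height(cloud, frame)
  top <- max(z)
  if (cot > top) stop("inconsistent reference: cotyledon node above canopy top")
  canopy_height <- top - cot

  # ground-plane projection: complete an orthonormal basis around the axis
  ax <- frame$vertical_axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  xy <- cloud$positions %*% cbind(e1, e2)
  rect <- min_area_rectangle(xy)

  # stem axis: vertical line through the centroid of the lowest 10% of points
  low <- z <= stats::quantile(z, 0.10)
  axis_xy <- colMeans(xy[low, , drop = FALSE])
  d2 <- (xy[, 1] - axis_xy[1])^2 + (xy[, 2] - axis_xy[2])^2
  near_stem <- d2 <= stem_radius_cm^2
  apex <- if (any(near_stem)) max(z[near_stem]) else max(z[low])
  plant_height <- apex - cot

  rec <- data.frame(variety = variety, stage = stage, days = days,
                    plant_length_cm = rect$length,
                    plant_width_cm = rect$width,
                    plant_height_cm = plant_height,
                    canopy_height_cm = canopy_height,
                    canopy_area_cm2 = rect$length * rect$width,
                    plant_volume_dm3 = rect$length * rect$width *
                      canopy_height / 1000)
  attr(rec, "ground_z") <- min(z)
  attr(rec, "cotyledon_z") <- cot
  class(rec) <- c("trait_record", "data.frame")
  rec
}
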