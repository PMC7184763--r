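#' Parametric synthetic plant specification
#'
#' Describes a stand-in potted plant with known bounding dimensions: a
#' vertical stem (cylinder) topped by the growing point, ellipsoidal leaf
#' lobes whose horizontal extremes touch the corners of the stated footprint
#' rectangle, and a top lobe that reaches the canopy top. Every trait the
#' extractor should recover is therefore known exactly from the spec.
#'
#' @param footprint_length_cm,footprint_width_cm Sides of the ground-plane
#'   bounding rectangle (length >= width enforced by swapping).
#' @param canopy_top_cm Height of the highest point of the plant (cm above
#'   ground).
#' @param cotyledon_cm Height of the cotyledon node (cm above ground).
#' @param apex_cm Height of the stem growing point; must satisfy
#'   `cotyledon < apex <= canopy_top`.
#' @param n_leaves Number of leaf lobes (>= 5: four corner lobes + top lobe;
#'   extras are placed at random azimuths strictly inside the footprint).
#' @param seed Random seed used by [make_plant_cloud()].
#' @return Object of class `"plant_spec"`.
#' @export
plant_spec <- function(footprint_length_cm = 40, footprint_width_cm = 30,
                       canopy_top_cm = 60, cotyledon_cm = 5,
                       apex_cm = 58, n_leaves = 8, seed = 1) {
  if (footprint_length_cm < footprint_width_cm) {
    tmp <- footprint_length_cm
    footprint_length_cm <- footprint_width_cm
    footprint_width_cm <- tmp
  }
  if (!(footprint_length_cm > 0 && footprint_width_cm > 0))
    stop("footprint must be positive")
  if (!(cotyledon_cm < apex_cm)) stop("cotyledon node must lie below the apex")
  if (!(apex_cm <= canopy_top_cm)) stop("apex must not exceed the canopy top")
  if (n_leaves < 5) stop("need at least 5 leaf lobes")
  structure(list(footprint_length_cm = footprint_length_cm,
                 footprint_width_cm = footprint_width_cm,
                 canopy_top_cm = canopy_top_cm, cotyledon_cm = cotyledon_cm,
                 apex_cm = apex_cm, n_leaves = n_leaves, seed = seed),
            class = "plant_spec")
}

sample_ellipsoid <- function(n, center, semi) {
  # uniform directions, pushed to the surface; outward analytic normals
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  p <- sweep(u, 2, semi, "*")
  p <- sweep(p, 2, center, "+")
  nrm <- sweep(u, 2, semi, "/")  # gradient of sum((x-c)^2/a^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  list(points = p, normals = nrm)
}

#' Generate a synthetic plant point cloud with exact trait ground truth
#'
#' Samples the plant surface described by a [plant_spec()]: stem cylinder
#' from the cotyledon node to the apex (the hypocotyl below the node is
#' hidden by the pot rim, so the cloud's lowest points sit at the node), four
#' leaf lobes whose outermost points touch the footprint corners, one top
#' lobe reaching the canopy top, and any extra lobes strictly inside. All
#' samples carry analytic outward normals and leaf-green / stem-brown
#' colours.
#'
#' @param spec [plant_spec()].
#' @param n Total number of surface samples (>= 500).
#' @return List: `cloud` ([point_cloud()]) and `truth` (the exact
#'   trait-record data.frame implied by the spec).
#' @export
make_plant_cloud <- function(spec, n = 20000) {
  if (n < 500) stop("need at least 500 samples")
  with_seed(spec$seed, {
    L <- spec$footprint_length_cm; W <- spec$footprint_width_cm
    z0 <- spec$cotyledon_cm; za <- spec$apex_cm; zt <- spec$canopy_top_cm
    stem_r <- 0.5
    n_stem <- max(100, round(0.25 * n))
    # stem: lateral surface + a small apex cap ring so the growing point is hit
    th <- stats::runif(n_stem, 0, 2 * pi)
    zz <- stats::runif(n_stem, z0, za)
    stem_p <- cbind(stem_r * cos(th), stem_r * sin(th), zz)
    stem_n <- cbind(cos(th), sin(th), 0)
    cap <- cbind(stem_r * 0.3 * cos(th[1:50]), stem_r * 0.3 * sin(th[1:50]),
                 rep(za, 50))
    cap_n <- matrix(rep(c(0, 0, 1), each = 50), 50, 3)
    stem_p <- rbind(stem_p, cap, c(0, 0, za))
    stem_n <- rbind(stem_n, cap_n, c(0, 0, 1))

    corners <- rbind(c(L / 2, W / 2), c(-L / 2, W / 2),
                     c(-L / 2, -W / 2), c(L / 2, -W / 2))
    lobes <- list()
    span <- zt - z0
    # leaf lobes live in the upper canopy (bottoms above 0.45 * span) so the
    # lowest tenth of the cloud is stem-only, as on a real potted plant where
    # the lower stem is bare
    fz <- c(0.62, 0.70, 0.78, 0.86)
    for (k in 1:4) {
      v <- corners[k, ]
      d <- sqrt(sum(v^2))
      a <- 0.35 * d                      # semi-axis toward the corner
      cen2 <- v * (1 - a / d)            # tip exactly at the corner
      b <- 0.28 * min(L, W) / 2
      cz <- z0 + fz[k] * span
      csemi <- min(0.17 * span, (zt - cz) * 0.95, (fz[k] - 0.45) * span)
      dir <- v / d
      lobes[[k]] <- list(center = c(cen2, cz),
                         semi = c(a, b, csemi), dir = dir, corner = k)
    }
    # top lobe: reaches the canopy top, offset from the stem axis so the
    # apex cylinder test cannot confuse it with the growing point
    top_off <- pmin(c(L, W), c(L, W)) / 4
    top_semi <- c(min(L / 6, top_off[1] * 0.9), min(W / 6, top_off[2] * 0.9),
                  span * 0.12)
    top_cen <- c(top_off[1], 0, zt - top_semi[3])
    n_extra <- spec$n_leaves - 5
    extra <- list()
    if (n_extra > 0) {
      az <- stats::runif(n_extra, 0, 2 * pi)
      rad <- stats::runif(n_extra, 0.25, 0.6)
      for (k in seq_len(n_extra)) {
        cen <- c(rad[k] * L / 2 * 0.7 * cos(az[k]),
                 rad[k] * W / 2 * 0.7 * sin(az[k]),
                 z0 + stats::runif(1, 0.58, 0.82) * span)
        extra[[k]] <- list(center = cen,
                           semi = c(L / 10, W / 10, span / 10))
      }
    }

    n_leaf_pts <- n - nrow(stem_p)
    all_lobes <- c(lobes, list(list(center = top_cen, semi = top_semi)), extra)
    per <- rep(floor(n_leaf_pts / length(all_lobes)), length(all_lobes))
    per[1] <- per[1] + n_leaf_pts - sum(per)
    P <- stem_p; N <- stem_n
    for (i in seq_along(all_lobes)) {
      lo <- all_lobes[[i]]
      s <- sample_ellipsoid(per[i], lo$center, lo$semi)
      # rotate corner lobes so the long semi-axis points at the corner
      if (!is.null(lo$dir)) {
        ct <- lo$dir[1]; st <- lo$dir[2]
        Rz <- rbind(c(ct, -st, 0), c(st, ct, 0), c(0, 0, 1))
        cen <- lo$center
        s$points <- sweep(sweep(s$points, 2, cen) %*% t(Rz), 2, cen, "+")
        s$normals <- s$normals %*% t(Rz)
        # pin the outermost sample exactly on the footprint corner
        s$points[1, ] <- cen + c(lo$semi[1] * lo$dir, 0)
        s$normals[1, ] <- c(lo$dir, 0)
      }
      if (i == 5) {  # top lobe: pin its pole on the canopy top
        s$points[1, ] <- lo$center + c(0, 0, lo$semi[3])
        s$normals[1, ] <- c(0, 0, 1)
      }
      P <- rbind(P, s$points); N <- rbind(N, s$normals)
    }
    # clamp tiny sampling overshoots into the stated bounding box
    P[, 1] <- pmin(pmax(P[, 1], -L / 2), L / 2)
    P[, 2] <- pmin(pmax(P[, 2], -W / 2), W / 2)
    P[, 3] <- pmin(P[, 3], zt)
    n_stem_all <- nrow(stem_p)
    cols <- rbind(
      matrix(rep(c(120, 90, 40), each = n_stem_all), n_stem_all, 3),
      cbind(40 + stats::runif(n - n_stem_all, 0, 40),
            130 + stats::runif(n - n_stem_all, 0, 60),
            30 + stats::runif(n - n_stem_all, 0, 30)))
    cloud <- point_cloud(P, colors = round(cols),
                         normals = N / sqrt(rowSums(N^2)))
    truth <- data.frame(variety = NA_character_, stage = NA_character_,
                        days = NA_real_,
                        plant_length_cm = L, plant_width_cm = W,
                        plant_height_cm = za - z0,
                        canopy_height_cm = zt - z0,
                        canopy_area_cm2 = L * W,
                        plant_volume_dm3 = L * W * (zt - z0) / 1000)
    list(cloud = cloud, truth = truth, spec = spec)
  })
}

#' Logistic growth-series specification
#'
#' @param params Named list per trait: each element a list/vector with `n0`,
#'   `k`, `r` (trait units and 1/day). Used as the generator's ground truth.
#' @param days Observation days after seedling emergence; default 9 time
#'   points spanning the season, emulating determinations at the nine stages
#'   V3, V4, R1, R2, R3, R5, R6, R7, R8.
#' @param noise_sd_frac Additive Gaussian noise standard deviation as a
#'   fraction of each trait's `k`.
#' @param seed Random seed.
#' @return Object of class `"growth_spec"`.
#' @export
growth_spec <- function(params = list(
                          plant_height_cm = list(n0 = 8, k = 85, r = 0.12),
                          canopy_height_cm = list(n0 = 9, k = 90, r = 0.11)),
                        days = c(20, 27, 38, 48, 58, 75, 90, 103, 118),
                        noise_sd_frac = 0.02, seed = 1) {
  for (p in params) check_logistic_params(p[["n0"]], p[["k"]], p[["r"]])
  stopifnot(all(diff(days) > 0), noise_sd_frac >= 0)
  structure(list(params = params, days = as.numeric(days),
                 noise_sd_frac = noise_sd_frac, seed = seed),
            class = "growth_spec")
}

#' Generate noisy logistic trait series
#'
#' Evaluates each trait's logistic curve at the specification's observation
#' days and adds Gaussian noise with standard deviation `noise_sd_frac * K`,
#' clipping at zero. The true parameters are retained for recovery tests.
#'
#' @param spec [growth_spec()].
#' @param variety Variety label attached to the series.
#' @return Named list of [trait_series()] (one per trait) with attribute
#'   `"truth"` = the generating parameters.
#' @export
make_growth_series <- function(spec, variety = "SYN1") {
  with_seed(spec$seed, {
    out <- lapply(names(spec$params), function(tr) {
      p <- spec$params[[tr]]
      mu <- logistic_value(p, spec$days)
      y <- pmax(0, mu + stats::rnorm(length(mu), 0, spec$noise_sd_frac * p[["k"]]))
      trait_series(variety, tr, spec$days, y)
    })
    names(out) <- names(spec$params)
    attr(out, "truth") <- spec$params
    out
  })
}

#' End-to-end synthetic validation of the reconstruction pipeline
#'
#' The desk-scale counterpart of validating extracted traits against manual
#' measurements: render seeded synthetic plants of varied size through the
#' full turntable rig, segment the blue-screen views, reconstruct each plant
#' from the masked correspondences, extract the four fingerprint traits and
#' correlate them against the generator's exact ground truth.
#'
#' @param n_plants Number of plants (default 10).
#' @param seed Base seed; plant i uses `seed + i`.
#' @param n_points Surface samples per plant.
#' @param intr Camera intrinsics (with image size).
#' @param rig [turntable_rig()].
#' @return List: `per_plant` (data.frame of extracted and true values) and
#'   `pearson` (named vector: Pearson r per trait across plants).
#' @export
synthetic_validation <- function(n_plants = 10, seed = 100, n_points = 8000,
                                 intr = intrinsics(400, 400, 160, 120,
                                                   width = 320, height = 240),
                                 rig = turntable_rig()) {
  traits <- c("plant_length_cm", "plant_width_cm", "plant_height_cm",
              "canopy_height_cm")
  rows <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    sp <- with_seed(seed + i, {
      L <- stats::runif(1, 25, 55)
      W <- L * stats::runif(1, 0.6, 0.95)
      top <- stats::runif(1, 35, 75)
      cot <- stats::runif(1, 3, 7)
      plant_spec(L, W, top, cot, apex_cm = top - stats::runif(1, 1, 4),
                 n_leaves = sample(6:9, 1), seed = seed + i)
    })
    plant <- make_plant_cloud(sp, n_points)
    rs <- render_views(plant$cloud, rig, intr, n_dots = 1500,
                       seed = seed + i)
    masks <- lapply(rs$images, segment_blue_screen)
    cameras <- list(intr = intr, views = rs$poses)
    cloud <- build_cloud(rs$images, masks, cameras,
                         ground_truth_detector(rs))
    rec <- extract_traits(cloud,
                          ground_frame(cotyledon_height_cm = sp$cotyledon_cm))
    out <- data.frame(plant = i)
    for (tr in traits) {
      out[[paste0(tr, "_extracted")]] <- rec[[tr]]
      out[[paste0(tr, "_true")]] <- plant$truth[[tr]]
    }
    rows[[i]] <- out
  }
  per_plant <- do.call(rbind, rows)
  pearson <- vapply(traits, function(tr)
    pearson_r(per_plant[[paste0(tr, "_extracted")]],
              per_plant[[paste0(tr, "_true")]]), numeric(1))
  list(per_plant = per_plant, pearson = pearson)
}
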