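# Pipeline orchestration: calibrate -> preprocess -> reconstruct -> mesh ->
# traits -> growth, with per-stage skipping when an output already exists.

default_config <- function() {
  list(
    paths = list(images_dir = NULL, calib_dir = NULL, masks_dir = NULL,
                 correspondences_csv = NULL, traits_csv_in = NULL,
                 out_dir = NULL),
    segmentation = list(tau = 30, min_area = 100, denoise = FALSE),
    ransac = list(iterations = 1000, threshold = 2, seed = 42),
    rig = list(rings = 4, stops = 15, elevations_deg = c(10, 15, 20, 25),
               distance_cm = 120, look_at = c(0, 0, 25)),
    reconstruction = list(epipolar_px = 1, reproj_px = 1,
                          merge_voxel_cm = 0.1),
    octree = list(depth = 5),
    traits = list(cotyledon_cm = NULL, stem_radius_cm = 2,
                  variety = "PLANT", stage = NA_character_, days = NA_real_),
    optimizer = list(learning_rate = 1e-2, max_iter = 50000),
    seed = 42)
}

#' Validated pipeline configuration
#'
#' Deep-merges the given settings over the documented defaults; unknown keys
#' at either level are rejected, and the octree depth must be 3..9.
#'
#' @param ... Named blocks (`paths`, `segmentation`, `ransac`, `rig`,
#'   `reconstruction`, `octree`, `traits`, `optimizer`, `seed`), each a list
#'   of the keys shown by `str(pipeline_config())`.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    if (is.list(base[[blk]])) {
      bad2 <- setdiff(names(user[[blk]]), names(base[[blk]]))
      if (length(bad2))
        stop("unknown config key(s) in ", blk, ": ",
             paste(bad2, collapse = ", "))
      base[[blk]][names(user[[blk]])] <- user[[blk]]
    } else {
      base[[blk]] <- user[[blk]]
    }
  }
  d <- base$octree$depth
  if (!is.numeric(d) || d < 3 || d > 9)
    stop("octree depth must be between 3 and 9")
  structure(base, class = "pipeline_config")
}

read_json_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_log <- function(stage, msg, t0 = NULL) {
  el <- if (is.null(t0)) "" else sprintf(" [%.2fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[%s] %s%s", stage, msg, el))
}

list_pngs <- function(dir) {
  f <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(f)) stop("no PNG images in ", dir)
  f
}

#' Run the full reconstruction-and-analysis pipeline
#'
#' Executes calibrate, preprocess (denoise + segment), reconstruct, mesh,
#' traits and growth in order, writing `cameras.json`, mask PNGs,
#' `cloud.ply`, `mesh.obj`, `traits.csv`, `fits.json` and `fp.csv` under the
#' configured output directory. A stage whose output already exists is
#' skipped, so a pipeline can be resumed. Any stage failure halts with the
#' stage name and cause.
#'
#' @param config [pipeline_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$paths$out_dir
  if (is.null(out)) stop("config paths$out_dir is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  art <- list(cameras = file.path(out, "cameras.json"),
              masks = file.path(out, "masks"),
              cloud = file.path(out, "cloud.ply"),
              mesh = file.path(out, "mesh.obj"),
              traits = file.path(out, "traits.csv"),
              fits = file.path(out, "fits.json"),
              fingerprint = file.path(out, "fp.csv"))
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    tryCatch(fn(t0), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  # --- calibrate -----------------------------------------------------------
  if (file.exists(art$cameras)) {
    stage_log("calibrate", "cameras.json exists, skipping")
  } else run_stage("calibrate", function(t0) {
    if (is.null(config$paths$calib_dir))
      stop("no cameras.json and no calib_dir configured")
    target <- calibration_target()
    imgs <- list_pngs(config$paths$calib_dir)
    corr <- lapply(imgs, function(f)
      detect_target_points(read_image(f), target))
    calib <- calibrate_ransac(corr, target,
                              ransac_config(config$ransac$iterations,
                                            config$ransac$threshold,
                                            config$ransac$seed))
    write_cameras_json(calib, art$cameras)
    stage_log("calibrate", sprintf(
      "%d views, mean reprojection %.3f px, fx=%.1f",
      length(calib$views), calib$mean_reproj_error, calib$intr$fx), t0)
  })

  # --- preprocess ----------------------------------------------------------
  imgs <- list_pngs(config$paths$images_dir)
  if (dir.exists(art$masks) &&
      length(list.files(art$masks, pattern = "\\.png$")) == length(imgs)) {
    stage_log("preprocess", "masks exist, skipping")
  } else run_stage("preprocess", function(t0) {
    dir.create(art$masks, showWarnings = FALSE)
    for (f in imgs) {
      img <- read_image(f)
      if (isTRUE(config$segmentation$denoise)) img <- wavelet_denoise(img)
      m <- segment_blue_screen(img, config$segmentation$tau,
                               config$segmentation$min_area)
      write_mask(m, file.path(art$masks, basename(f)))
    }
    stage_log("preprocess", sprintf("%d masks written", length(imgs)), t0)
  })

  # --- reconstruct ---------------------------------------------------------
  if (file.exists(art$cloud)) {
    stage_log("reconstruct", "cloud.ply exists, skipping")
  } else run_stage("reconstruct", function(t0) {
    cams_file <- read_cameras_json(art$cameras)
    rig <- turntable_rig(config$rig$rings, config$rig$stops,
                         config$rig$elevations_deg, config$rig$distance_cm,
                         config$rig$look_at)
    cameras <- list(intr = cams_file$intr, views = rig_poses(rig))
    images <- lapply(imgs, read_image)
    masks <- lapply(list_pngs(art$masks), read_mask)
    if (is.null(config$paths$correspondences_csv))
      stop("correspondences_csv is required (interest-point matching is a ",
           "pluggable input)")
    matches <- utils::read.csv(config$paths$correspondences_csv)
    if (!is.null(cams_file$k1) && cams_file$k1 != 0) {
      # undo the calibrated radial distortion before triangulating
      ua <- radial_undistort(cbind(matches$ua, matches$va), cams_file$intr,
                             cams_file$k1)
      ub <- radial_undistort(cbind(matches$ub, matches$vb), cams_file$intr,
                             cams_file$k1)
      matches$ua <- ua[, 1]; matches$va <- ua[, 2]
      matches$ub <- ub[, 1]; matches$vb <- ub[, 2]
    }
    detector <- function(images, masks, cameras) matches
    cloud <- build_cloud(images, masks, cameras, detector,
                         config$reconstruction$epipolar_px,
                         config$reconstruction$reproj_px,
                         config$reconstruction$merge_voxel_cm)
    write_ply(cloud, art$cloud)
    stage_log("reconstruct", sprintf("%d points", nrow(cloud$positions)), t0)
  })

  # --- mesh ----------------------------------------------------------------
  if (file.exists(art$mesh)) {
    stage_log("mesh", "mesh.obj exists, skipping")
  } else run_stage("mesh", function(t0) {
    cloud <- read_ply(art$cloud)
    if (is.null(cloud$normals)) cloud <- estimate_normals(cloud)
    field <- solve_poisson(cloud, depth = config$octree$depth)
    mesh <- marching_tetrahedra(field)
    write_obj(mesh, art$mesh)
    stage_log("mesh", sprintf("%d triangles", nrow(mesh$faces)), t0)
  })

  # --- traits --------------------------------------------------------------
  if (file.exists(art$traits)) {
    stage_log("traits", "traits.csv exists, skipping")
  } else run_stage("traits", function(t0) {
    cloud <- read_ply(art$cloud)
    frame <- ground_frame(cotyledon_height_cm = config$traits$cotyledon_cm)
    rec <- extract_traits(cloud, frame, config$traits$stem_radius_cm,
                          variety = config$traits$variety,
                          stage = config$traits$stage,
                          days = config$traits$days)
    tab <- as.data.frame(rec)
    if (!is.null(config$paths$traits_csv_in))
      tab <- rbind(read_traits_csv(config$paths$traits_csv_in),
                   tab[, TRAIT_COLUMNS])
    write_traits_csv(tab, art$traits)
    stage_log("traits", sprintf("%d rows", nrow(tab)), t0)
  })

  # --- growth --------------------------------------------------------------
  if (file.exists(art$fits) && file.exists(art$fingerprint)) {
    stage_log("growth", "fits.json and fp.csv exist, skipping")
  } else run_stage("growth", function(t0) {
    tab <- read_traits_csv(art$traits)
    counts <- table(tab$variety[!is.na(tab$days)])
    fit_vars <- names(counts)[counts >= 4]
    fits <- if (length(fit_vars))
      fit_growth_table(tab[tab$variety %in% fit_vars, ],
                       learning_rate = config$optimizer$learning_rate,
                       max_iter = config$optimizer$max_iter)
    else list()
    write_fits_json(fits, art$fits)
    fp_tab <- tab[!is.na(tab$stage) & tab$stage != "", , drop = FALSE]
    if (nrow(fp_tab)) {
      fp <- fingerprint(fp_tab)
      utils::write.csv(cbind(fp$meta, as.data.frame(fp$values)),
                       art$fingerprint, row.names = FALSE)
    } else {
      utils::write.csv(data.frame(variety = character(), stage = character()),
                       art$fingerprint, row.names = FALSE)
    }
    stage_log("growth", sprintf("%d fits", length(fits)), t0)
  })

  invisible(art)
}
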