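# File formats: PLY point clouds and meshes (ASCII written; ASCII and
# binary_little_endian read), OBJ meshes, trait CSV tables and camera JSON.

#' Write a point cloud or mesh as ASCII PLY
#'
#' Positions are written at 9 significant digits; colors (uchar) and normals
#' (double) are included when present.
#'
#' @param x [point_cloud()] or [triangle_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  is_mesh <- inherits(x, "triangle_mesh")
  pos <- if (is_mesh) x$vertices else x$positions
  n <- nrow(pos)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  cols <- if (!is_mesh) x$colors else NULL
  nrms <- x$normals
  if (!is.null(nrms))
    hdr <- c(hdr, "property double nx", "property double ny",
             "property double nz")
  if (!is.null(cols))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  if (is_mesh)
    hdr <- c(hdr, sprintf("element face %d", nrow(x$faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  body <- format(pos, digits = 9, scientific = FALSE, trim = TRUE)
  rows <- paste(body[, 1], body[, 2], body[, 3])
  if (!is.null(nrms)) {
    nb <- format(nrms, digits = 9, scientific = FALSE, trim = TRUE)
    rows <- paste(rows, nb[, 1], nb[, 2], nb[, 3])
  }
  if (!is.null(cols)) {
    cb <- round(cols)
    rows <- paste(rows, cb[, 1], cb[, 2], cb[, 3])
  }
  out <- c(hdr, rows)
  if (is_mesh && nrow(x$faces) > 0)
    out <- c(out, paste(3, x$faces[, 1] - 1, x$faces[, 2] - 1,
                        x$faces[, 3] - 1))
  writeLines(out, path)
  invisible(path)
}

ply_type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                   short = 2, ushort = 2, int16 = 2, uint16 = 2,
                   int = 4, uint = 4, int32 = 4, uint32 = 4,
                   float = 4, float32 = 4, double = 8, float64 = 8)

#' Read a PLY file
#'
#' Accepts ASCII and binary_little_endian dialects; vertex properties
#' x/y/z/nx/ny/nz/red/green/blue are recognized, faces (triangles) when a
#' face element is present.
#'
#' @param path PLY path.
#' @return [point_cloud()] (no face element) or [triangle_mesh()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) stop("malformed PLY: no end_header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (hdr[1] != "ply") stop("malformed PLY header: missing magic")
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt)) stop("malformed PLY header: missing format")
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)
  elements <- list()
  cur <- NULL
  for (line in hdr) {
    if (grepl("^element ", line)) {
      p <- strsplit(line, " +")[[1]]
      cur <- p[2]
      elements[[cur]] <- list(count = as.integer(p[3]), props = list())
    } else if (grepl("^property ", line) && !is.null(cur)) {
      p <- strsplit(line, " +")[[1]]
      if (p[2] == "list") {
        elements[[cur]]$props[[p[5]]] <- list(list = TRUE,
                                              count_type = p[3],
                                              item_type = p[4])
      } else {
        elements[[cur]]$props[[p[3]]] <- list(list = FALSE, type = p[2])
      }
    }
  }
  if (is.null(elements$vertex)) stop("malformed PLY: missing vertex element")
  read_scalar <- function(type, n = 1) {
    sz <- ply_type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "numeric", n, size = sz, endian = "little")
    else
      readBin(con, "integer", n, size = sz, endian = "little",
              signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  verts <- NULL; faces <- NULL
  if (binary) {
    for (el in names(elements)) {
      e <- elements[[el]]
      if (!any(vapply(e$props, `[[`, TRUE, "list"))) {
        types <- vapply(e$props, `[[`, "", "type")
        vals <- matrix(0, e$count, length(types))
        # row-wise read (properties may mix sizes)
        for (i in seq_len(e$count))
          for (j in seq_along(types)) vals[i, j] <- read_scalar(types[j])
        colnames(vals) <- names(e$props)
        if (el == "vertex") verts <- vals
      } else {
        pr <- e$props[[1]]
        fl <- vector("list", e$count)
        for (i in seq_len(e$count)) {
          cnt <- read_scalar(pr$count_type)
          fl[[i]] <- read_scalar(pr$item_type, cnt)
        }
        if (el == "face") faces <- fl
      }
    }
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(txt)]
    nv <- elements$vertex$count
    if (length(txt) < nv) stop("malformed PLY: vertex element truncated")
    vv <- utils::read.table(text = txt[seq_len(nv)])
    if (ncol(vv) != length(elements$vertex$props))
      stop("malformed PLY: vertex property count mismatch")
    verts <- as.matrix(vv)
    colnames(verts) <- names(elements$vertex$props)
    if (!is.null(elements$face)) {
      nf <- elements$face$count
      if (length(txt) < nv + nf) stop("malformed PLY: face element truncated")
      faces <- lapply(strsplit(txt[nv + seq_len(nf)], " +"), function(p) {
        as.integer(p[-1])[seq_len(as.integer(p[1]))]
      })
    }
  }
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(verts)))
    stop("malformed PLY: vertex element lacks x/y/z")
  pos <- verts[, need, drop = FALSE]
  nrms <- if (all(c("nx", "ny", "nz") %in% colnames(verts)))
    verts[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  if (!is.null(nrms)) {
    l <- sqrt(rowSums(nrms^2)); l[l == 0] <- 1
    nrms <- nrms / l
  }
  cols <- if (all(c("red", "green", "blue") %in% colnames(verts)))
    verts[, c("red", "green", "blue"), drop = FALSE] else NULL
  if (is.null(faces)) {
    point_cloud(pos, colors = cols, normals = nrms)
  } else {
    fm <- do.call(rbind, lapply(faces, function(f) f[1:3] + 1L))
    triangle_mesh(pos, fm)
  }
}

#' Write a mesh as Wavefront OBJ
#' @param mesh [triangle_mesh()].
#' @param path Output path.
#' @export
write_obj <- function(mesh, path) {
  v <- sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
               mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
               mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

TRAIT_COLUMNS <- c("variety", "stage", "days", "plant_length_cm",
                   "plant_width_cm", "plant_height_cm", "canopy_height_cm",
                   "canopy_area_cm2", "plant_volume_dm3")

#' Read / write the trait table CSV
#'
#' Schema: `variety`, `stage` (opaque growth-stage label), `days` (days after
#' seedling emergence, numeric) and the six trait columns in cm / cm^2 / dm^3.
#'
#' @param path CSV path.
#' @return `read_traits_csv()`: data.frame with typed columns.
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRAIT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  suppressWarnings(d <- as.numeric(df$days))
  if (any(is.na(d) & !is.na(df$days)))
    stop("days column is not numeric")
  df$days <- d
  df$stage <- as.character(df$stage)
  df$variety <- as.character(df$variety)
  df
}

#' @rdname read_traits_csv
#' @param traits Data.frame with the schema columns.
#' @export
write_traits_csv <- function(traits, path) {
  missing_cols <- setdiff(TRAIT_COLUMNS, names(traits))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.csv(traits[, TRAIT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Serialize / load camera parameters as JSON
#'
#' Schema: `{fx, fy, u0, v0, k1, views: [{R (row-major 9), t (3)}]}`.
#'
#' @param calib A `"camera_calibration"` or list with `intr`, `views`, `k1`.
#' @param path JSON path.
#' @export
write_cameras_json <- function(calib, path) {
  obj <- list(fx = calib$intr$fx, fy = calib$intr$fy,
              u0 = calib$intr$u0, v0 = calib$intr$v0,
              k1 = calib$k1 %||% 0,
              views = lapply(calib$views, function(e)
                list(R = as.numeric(t(e$R)), t = as.numeric(e$t))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras_json
#' @export
read_cameras_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  views <- lapply(obj$views, function(v)
    extrinsics(matrix(unlist(v$R), 3, 3, byrow = TRUE), unlist(v$t)))
  list(intr = intrinsics(obj$fx, obj$fy, obj$u0, obj$v0),
       k1 = obj$k1, views = views)
}

#' Export logistic fits as JSON
#' @param fits Named list of [fit_logistic()] results (names `variety.trait`).
#' @param path JSON path.
#' @export
write_fits_json <- function(fits, path) {
  obj <- lapply(fits, function(f)
    list(variety = f$series$variety, trait = f$series$trait,
         n0 = f$n0, k = f$k, r = f$r, rss = f$rss,
         t_inflection = f$t_inflection, rate_max = f$rate_max,
         fitted_max = f$fitted_max, converged = f$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
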