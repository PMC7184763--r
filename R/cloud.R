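#' Point cloud container
#'
#' Oriented, optionally coloured 3D samples in the world frame (cm; z up,
#' turntable center at the origin, ground plane z = 0).
#'
#' @param positions N x 3 numeric matrix (cm), all finite.
#' @param colors Optional N x 3 matrix of 8-bit RGB values.
#' @param normals Optional N x 3 matrix of unit normals (checked to 1e-6).
#' @return Object of class `"point_cloud"`.
#' @export
point_cloud <- function(positions, colors = NULL, normals = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  n <- nrow(positions)
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    stopifnot(nrow(colors) == n, ncol(colors) == 3,
              all(colors >= 0), all(colors <= 255))
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    stopifnot(nrow(normals) == n, ncol(normals) == 3)
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must be unit length (within 1e-6)")
  }
  structure(list(positions = positions, colors = colors, normals = normals),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point cloud: %d points%s%s\n", nrow(x$positions),
              if (!is.null(x$colors)) " + colors" else "",
              if (!is.null(x$normals)) " + normals" else ""))
  invisible(x)
}

#' Triangle mesh container
#'
#' @param vertices V x 3 numeric matrix (cm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param normals Optional per-vertex normals.
#' @return Object of class `"triangle_mesh"`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0)
    stopifnot(min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh [triangle_mesh()].
#' @return Area in cm^2.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Merge duplicate points on a voxel grid
#'
#' Replaces all points falling in the same cubic voxel by their centroid
#' (colors and normals averaged; normals re-normalized). `voxel_cm = 0`
#' returns the cloud unchanged.
#'
#' @param cloud [point_cloud()].
#' @param voxel_cm Voxel edge length (cm).
#' @return Merged [point_cloud()].
#' @export
merge_voxels <- function(cloud, voxel_cm = 0.1) {
  if (voxel_cm <= 0) return(cloud)
  p <- cloud$positions
  key <- paste(floor(p[, 1] / voxel_cm), floor(p[, 2] / voxel_cm),
               floor(p[, 3] / voxel_cm))
  idx <- split(seq_len(nrow(p)), key)
  agg <- function(m) {
    if (is.null(m)) return(NULL)
    out <- t(vapply(idx, function(i) colMeans(m[i, , drop = FALSE]),
                    numeric(3)))
    out
  }
  pos <- agg(p)
  nrm <- agg(cloud$normals)
  if (!is.null(nrm)) {
    len <- sqrt(rowSums(nrm^2)); len[len < 1e-12] <- 1
    nrm <- nrm / len
  }
  col <- agg(cloud$colors)
  point_cloud(pos, colors = col, normals = nrm)
}
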