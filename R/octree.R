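#' Build an adaptive octree over a point cloud
#'
#' The root node is the cloud's (isotropically padded) bounding cube; every
#' node containing samples is subdivided into its eight children until the
#' requested depth, so each sample ends in exactly one depth-`depth` leaf.
#'
#' @param cloud [point_cloud()] (non-empty).
#' @param depth Maximum depth, between 3 and 9.
#' @param pad Isotropic padding factor on the bounding cube (default 1.1).
#' @return Object of class `"octree"`: nested nodes, each a list with
#'   `center`, `width`, `depth`, `sample_idx` (leaf) or `children` (length-8
#'   list, some possibly `NULL`).
#' @export
build_octree <- function(cloud, depth, pad = 1.1) {
  if (nrow(cloud$positions) == 0) stop("no samples")
  if (depth < 3 || depth > 9) stop("depth must be between 3 and 9")
  p <- cloud$positions
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  center <- (lo + hi) / 2
  width <- max(hi - lo, 1e-9) * pad
  build_node <- function(center, width, d, idx) {
    node <- list(center = center, width = width, depth = d)
    if (d == depth || length(idx) == 0) {
      node$sample_idx <- idx
      return(node)
    }
    children <- vector("list", 8)
    for (ci in 0:7) {
      sgn <- c(bitwAnd(ci, 1), bitwAnd(bitwShiftR(ci, 1), 1),
               bitwAnd(bitwShiftR(ci, 2), 1)) * 2 - 1
      ccen <- center + sgn * width / 4
      inside <- idx[
        p[idx, 1] >= ccen[1] - width / 4 & p[idx, 1] < ccen[1] + width / 4 &
        p[idx, 2] >= ccen[2] - width / 4 & p[idx, 2] < ccen[2] + width / 4 &
        p[idx, 3] >= ccen[3] - width / 4 & p[idx, 3] < ccen[3] + width / 4]
      if (length(inside) > 0)
        children[[ci + 1]] <- build_node(ccen, width / 2, d + 1, inside)
    }
    node$children <- children
    node
  }
  root <- build_node(center, width, 0, seq_len(nrow(p)))
  structure(list(root = root, depth = depth, pad = pad), class = "octree")
}

#' Collect all leaves of an octree at a given depth
#' @param tree [build_octree()] result.
#' @param depth Depth of the leaves wanted (default the tree's maximum).
#' @return data.frame: cx, cy, cz, width, n_samples.
#' @export
octree_leaves <- function(tree, depth = tree$depth) {
  acc <- list()
  walk <- function(node) {
    if (is.null(node)) return(invisible())
    if (node$depth == depth && !is.null(node$sample_idx)) {
      acc[[length(acc) + 1]] <<- data.frame(
        cx = node$center[1], cy = node$center[2], cz = node$center[3],
        width = node$width, n_samples = length(node$sample_idx))
    }
    if (!is.null(node$children)) lapply(node$children, walk)
    invisible()
  }
  walk(tree$root)
  do.call(rbind, acc)
}

# Which depth-`depth` leaf (if any) contains each sample? Used by tests.
octree_locate <- function(tree, cloud) {
  leaves <- octree_leaves(tree)
  p <- cloud$positions
  counts <- integer(nrow(p))
  for (i in seq_len(nrow(leaves))) {
    w2 <- leaves$width[i] / 2
    inside <- p[, 1] >= leaves$cx[i] - w2 & p[, 1] < leaves$cx[i] + w2 &
      p[, 2] >= leaves$cy[i] - w2 & p[, 2] < leaves$cy[i] + w2 &
      p[, 3] >= leaves$cz[i] - w2 & p[, 3] < leaves$cz[i] + w2
    counts <- counts + inside
  }
  counts
}
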