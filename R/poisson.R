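# Poisson surface reconstruction on the complete depth-D node grid: splat
# oriented samples into a smoothed indicator-gradient field V, assemble the
# Galerkin system <grad phi, grad F_o> = <V, grad F_o> over tensor-product
# B-spline node functions, solve by Gauss-Seidel, and extract the isosurface
# with marching tetrahedra.

#' B-spline basis specification for the Poisson solve
#'
#' The node function is a translate/dilate of a base profile obtained by
#' convolving the unit box filter with itself: `n = 3` box factors give the
#' quadratic B-spline (compact support of 3 cells, unit integral), the
#' standard smoothing choice for the indicator gradient.
#'
#' @param n Number of box-filter factors (only `n = 3` is implemented).
#' @return Object of class `"basis_spec"` with `n`, `support` (cells) and
#'   `profile` (the 1D function).
#' @export
basis_spec <- function(n = 3) {
  if (n != 3) stop("only the n = 3 (quadratic B-spline) basis is implemented")
  structure(list(n = n, support = 3, profile = bspline2), class = "basis_spec")
}

# Quadratic B-spline (three box convolutions), support [-1.5, 1.5], unit
# integral; and its derivative.
bspline2 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 0.5, 0.75 - ax^2,
         ifelse(ax < 1.5, 0.5 * (1.5 - ax)^2, 0))
}

bspline2_deriv <- function(x) {
  ifelse(abs(x) < 0.5, -2 * x,
         ifelse(x >= 0.5 & x < 1.5, -(1.5 - x),
                ifelse(x <= -0.5 & x > -1.5, (1.5 + x), 0)))
}

# cubic B-spline (for the optional 64-node splat), support [-2, 2]
bspline3 <- function(x) {
  ax <- abs(x)
  ifelse(ax < 1, (4 - 6 * ax^2 + 3 * ax^3) / 6,
         ifelse(ax < 2, (2 - ax)^3 / 6, 0))
}

# 1D inner-product tables of the dimensionless quadratic B-spline:
# mu_k = int F(x) F(x-k), sigma_k = int F'(x) F'(x-k), gamma_k = int F(x-k) F'(x),
# k = -2..2; computed once by numerical quadrature.
basis_tables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    quad <- function(f) stats::integrate(f, -4, 4, rel.tol = 1e-12,
                                         subdivisions = 2000L)$value
    ks <- -2:2
    mu <- vapply(ks, function(k) quad(function(x) bspline2(x) * bspline2(x - k)),
                 0)
    sg <- vapply(ks, function(k)
      quad(function(x) bspline2_deriv(x) * bspline2_deriv(x - k)), 0)
    gm <- vapply(ks, function(k)
      quad(function(x) bspline2(x - k) * bspline2_deriv(x)), 0)
    cache <<- list(k = ks, mu = mu, sigma = sg, gamma = gm)
    cache
  }
})

# Uniform depth-D node grid over the (padded) bounding cube of a cloud.
field_grid <- function(cloud, depth, pad = 1.3) {
  p <- cloud$positions
  lo <- apply(p, 2, min); hi <- apply(p, 2, max)
  center <- (lo + hi) / 2
  W <- max(hi - lo, 1e-9) * pad
  n <- 2L^depth
  h <- W / n
  origin <- center - W / 2    # corner of the cube
  list(center = center, width = W, n = n, h = h, origin = origin,
       depth = depth)
}

#' Splat oriented samples into the node vector field
#'
#' Distributes each sample's unit normal over its neighbouring depth-D nodes
#' with interpolation weights that sum to one per sample: trilinear over the
#' 8 nearest node centers (default) or tricubic B-spline over 64 nodes.
#'
#' @param cloud [point_cloud()] with unit normals.
#' @param grid Node grid (internal; made by `solve_poisson` from the cloud),
#'   a list with `origin`, `h`, `n`.
#' @param method `"trilinear"` or `"tricubic"`.
#' @return List of three n^3 arrays `vx`, `vy`, `vz` (node coefficients of
#'   the vector field) with attribute `weight_sums` (per-sample totals, all
#'   1 up to rounding).
#' @export
splat_vector_field <- function(cloud, grid, method = c("trilinear", "tricubic")) {
  method <- match.arg(method)
  if (is.null(cloud$normals)) stop("normals required")
  p <- cloud$positions
  nrm <- cloud$normals
  n <- grid$n
  g <- sweep(p, 2, grid$origin) / grid$h - 0.5  # node-index coordinates
  acc <- list(vx = numeric(n^3), vy = numeric(n^3), vz = numeric(n^3))
  wsum <- numeric(nrow(p))
  if (method == "trilinear") {
    base <- floor(g); fr <- g - base
    offs <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))
    wfun <- function(fr, d) if (d == 0) 1 - fr else fr
  } else {
    base <- floor(g) - 1; fr <- g - floor(g)
    offs <- as.matrix(expand.grid(dx = 0:3, dy = 0:3, dz = 0:3))
    wfun <- function(fr, d) bspline3(fr + 1 - d)
  }
  for (r in seq_len(nrow(offs))) {
    ix <- base[, 1] + offs[r, 1]; iy <- base[, 2] + offs[r, 2]
    iz <- base[, 3] + offs[r, 3]
    w <- wfun(fr[, 1], offs[r, 1]) * wfun(fr[, 2], offs[r, 2]) *
      wfun(fr[, 3], offs[r, 3])
    ok <- ix >= 0 & ix < n & iy >= 0 & iy < n & iz >= 0 & iz < n & w > 0
    wsum <- wsum + ifelse(ok, w, 0)
    if (!any(ok)) next
    idx <- ix[ok] + n * iy[ok] + n^2 * iz[ok] + 1
    for (comp in 1:3) {
      add <- rowsum((w[ok]) * nrm[ok, comp], idx)
      ii <- as.integer(rownames(add))
      acc[[comp]][ii] <- acc[[comp]][ii] + add
    }
  }
  out <- list(vx = array(acc$vx, c(n, n, n)),
              vy = array(acc$vy, c(n, n, n)),
              vz = array(acc$vz, c(n, n, n)))
  attr(out, "weight_sums") <- wsum
  attr(out, "method") <- method
  out
}

# Apply a banded 1D operator (5-diagonal Toeplitz with entries tab[k+3],
# k = -2..2) along one axis of a 3D array.
apply_axis <- function(arr, tab, axis) {
  n <- dim(arr)[1]
  B <- matrix(0, n, n)
  for (k in -2:2) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    B[cbind(i[ok], j[ok])] <- tab[k + 3]
  }
  m <- dim(arr)
  if (axis == 1) {
    out <- B %*% matrix(arr, m[1], m[2] * m[3])
    array(out, m)
  } else if (axis == 2) {
    perm <- aperm(arr, c(2, 1, 3))
    out <- B %*% matrix(perm, m[2], m[1] * m[3])
    aperm(array(out, c(m[2], m[1], m[3])), c(2, 1, 3))
  } else {
    perm <- aperm(arr, c(3, 1, 2))
    out <- B %*% matrix(perm, m[3], m[1] * m[2])
    aperm(array(out, c(m[3], m[1], m[2])), c(2, 3, 1))
  }
}

banded_1d <- function(n, tab) {
  Matrix::bandSparse(n, n, k = -2:2,
                     diagonals = lapply(-2:2, function(k)
                       rep(tab[k + 3], n - abs(k))))
}

#' Gauss-Seidel solve of a linear system
#'
#' Iterates `x_i <- (b_i - sum_{j<i} a_ij x_j - sum_{j>i} a_ij x_j) / a_ii`
#' (i.e. `X^(i+1) = D^{-1} (L X^(i+1) + U X^(i) + b)` in matrix-splitting
#' form) until the relative residual drops below `tol` or the sweep budget is
#' exhausted. Requires nonzero diagonal entries; converges for any symmetric
#' positive definite system.
#'
#' @param A Square matrix (dense, or any `Matrix` sparse class).
#' @param b Right-hand side.
#' @param tol Relative-residual tolerance (default 1e-8).
#' @param max_iter Sweep budget (default 10000).
#' @param x0 Starting vector (default zeros).
#' @return List: `x`, `residual` (relative), `iterations`, `converged`.
#'   Warns when the budget is exhausted before `tol`.
#' @export
gauss_seidel_solve <- function(A, b, tol = 1e-8, max_iter = 10000,
                               x0 = NULL) {
  Ar <- as(as(as(A, "generalMatrix"), "RsparseMatrix"), "dMatrix")
  if (is.null(x0)) x0 <- numeric(length(b))
  res <- .gs_csr(Ar@p, Ar@j, Ar@x, as.numeric(b), as.numeric(x0),
                 tol, as.integer(max_iter))
  if (!res$converged)
    warning(sprintf(
      "Gauss-Seidel did not reach tol=%.1e in %d sweeps (residual %.3e)",
      tol, max_iter, res$residual))
  res
}

#' Poisson reconstruction of the implicit surface field
#'
#' Solves the Poisson problem `laplacian(phi) = div V` where `V` is the
#' smoothed indicator-gradient field splatted from the oriented samples:
#' Galerkin discretization over tensor-product quadratic B-spline node
#' functions on the complete depth-`depth` node grid, zero-Dirichlet outer
#' node layer (the padded bounding cube keeps the surface away from it), and
#' a Gauss-Seidel solve. The isovalue is the mean of `phi` over the input
#' samples.
#'
#' @param cloud [point_cloud()] with unit normals (see [estimate_normals()]
#'   when the cloud has none).
#' @param depth Grid depth D; the solve runs on `2^D` cells per axis.
#' @param basis [basis_spec()].
#' @param splat `"trilinear"` or `"tricubic"`.
#' @param pad Bounding-cube padding factor.
#' @param tol,max_iter Gauss-Seidel settings.
#' @return Object of class `"implicit_field"`: `grid`, `coeff` (n^3 array of
#'   node coefficients), `isovalue`, `solver` (residual/iterations), `basis`.
#' @export
solve_poisson <- function(cloud, depth = 5, basis = basis_spec(),
                          splat = "trilinear", pad = 1.3,
                          tol = 1e-8, max_iter = 10000) {
  if (is.null(cloud$normals)) stop("normals required")
  grid <- field_grid(cloud, depth, pad)
  n <- grid$n; h <- grid$h
  tabs <- basis_tables()
  V <- splat_vector_field(cloud, grid, splat)
  # b_o = <V, grad F_o>: per axis, gamma along that axis and (h mu) along
  # the other two
  Mh <- tabs$mu * h
  b_arr <- apply_axis(apply_axis(apply_axis(V$vx, tabs$gamma, 1), Mh, 2), Mh, 3) +
    apply_axis(apply_axis(apply_axis(V$vy, Mh, 1), tabs$gamma, 2), Mh, 3) +
    apply_axis(apply_axis(apply_axis(V$vz, Mh, 1), Mh, 2), tabs$gamma, 3)
  # stiffness A = S (x) M (x) M + M (x) S (x) M + M (x) M (x) S
  M1 <- banded_1d(n, Mh)
  S1 <- banded_1d(n, tabs$sigma / h)
  A <- Matrix::kronecker(M1, Matrix::kronecker(M1, S1)) +
    Matrix::kronecker(M1, Matrix::kronecker(S1, M1)) +
    Matrix::kronecker(S1, Matrix::kronecker(M1, M1))
  # zero-Dirichlet outer layer: solve on interior nodes only
  idx3 <- as.matrix(expand.grid(ix = 0:(n - 1), iy = 0:(n - 1),
                                iz = 0:(n - 1)))
  interior <- idx3[, 1] >= 1 & idx3[, 1] <= n - 2 &
    idx3[, 2] >= 1 & idx3[, 2] <= n - 2 &
    idx3[, 3] >= 1 & idx3[, 3] <= n - 2
  Ai <- A[interior, interior]
  bi <- as.numeric(b_arr)[interior]
  sol <- gauss_seidel_solve(Ai, bi, tol = tol, max_iter = max_iter)
  coeff <- numeric(n^3)
  coeff[interior] <- sol$x
  coeff <- array(coeff, c(n, n, n))
  field <- structure(list(grid = grid, coeff = coeff, basis = basis,
                          solver = sol[c("residual", "iterations",
                                         "converged")],
                          isovalue = NA_real_),
                     class = "implicit_field")
  field$isovalue <- mean(eval_field(field, cloud$positions))
  field
}

#' Evaluate the implicit function at arbitrary points
#' @param field [solve_poisson()] result.
#' @param points N x 3 matrix.
#' @return Numeric vector of phi values.
#' @export
eval_field <- function(field, points) {
  grid <- field$grid; n <- grid$n
  g <- sweep(as.matrix(points), 2, grid$origin) / grid$h - 0.5
  base <- floor(g) - 1
  out <- numeric(nrow(g))
  for (dx in 0:3) for (dy in 0:3) for (dz in 0:3) {
    ix <- base[, 1] + dx; iy <- base[, 2] + dy; iz <- base[, 3] + dz
    w <- bspline2(g[, 1] - ix) * bspline2(g[, 2] - iy) * bspline2(g[, 3] - iz)
    ok <- ix >= 0 & ix < n & iy >= 0 & iy < n & iz >= 0 & iz < n & w > 0
    if (!any(ok)) next
    idx <- ix[ok] + n * iy[ok] + n^2 * iz[ok] + 1
    out[ok] <- out[ok] + w[ok] * field$coeff[idx]
  }
  out
}

# phi on the (n+1)^3 cell-corner grid, by separable 1D evaluation.
corner_values <- function(field) {
  n <- field$grid$n
  # corner j (0..n) at origin + j h; node i centered at origin + (i+.5) h
  E <- outer(0:n, 0:(n - 1), function(j, i) bspline2(j - i - 0.5))
  m <- c(n, n, n)
  a <- E %*% matrix(field$coeff, n, n * n)                    # x axis
  a <- array(a, c(n + 1, n, n))
  perm <- aperm(a, c(2, 1, 3))
  a <- E %*% matrix(perm, n, (n + 1) * n)
  a <- aperm(array(a, c(n + 1, n + 1, n)), c(2, 1, 3))        # y axis
  perm <- aperm(a, c(3, 1, 2))
  a <- E %*% matrix(perm, n, (n + 1) * (n + 1))
  aperm(array(a, c(n + 1, n + 1, n + 1)), c(2, 3, 1))         # z axis
}

#' Extract the isosurface of an implicit field by marching tetrahedra
#'
#' Each grid cell is split into six tetrahedra; the sign pattern of
#' `phi - isovalue` on a tetrahedron's four corners emits 0-2 triangles with
#' vertices linearly interpolated along the crossing edges, and shared
#' vertices are welded. A field of constant sign yields an empty mesh.
#'
#' @param field [solve_poisson()] result, or a plain 3D array of corner
#'   values (then give `origin` and `h`).
#' @param isovalue Level to extract (default the field's stored isovalue).
#' @param origin,h Grid geometry when `field` is a plain array.
#' @return [triangle_mesh()].
#' @export
marching_tetrahedra <- function(field, isovalue = NULL, origin = NULL,
                                h = NULL) {
  if (inherits(field, "implicit_field")) {
    vals <- corner_values(field)
    if (is.null(isovalue)) isovalue <- field$isovalue
    origin <- field$grid$origin; h <- field$grid$h
  } else {
    vals <- field
    if (is.null(isovalue) || is.null(origin) || is.null(h))
      stop("plain-array input needs isovalue, origin and h")
  }
  d <- dim(vals)
  res <- .march_tets(as.numeric(vals), d[1] - 1L, d[2] - 1L, d[3] - 1L,
                     isovalue, as.numeric(origin), h)
  triangle_mesh(res$vertices, res$faces)
}

#' Estimate oriented normals for a raw point cloud
#'
#' PCA normal direction over the `k` nearest neighbours of each point;
#' orientation made globally consistent by propagation along a Euclidean
#' minimum spanning tree, then flipped (if needed) so normals point away
#' from the centroid on average.
#'
#' @param cloud [point_cloud()].
#' @param k Neighbourhood size (default 16).
#' @return The cloud with unit normals attached.
#' @export
estimate_normals <- function(cloud, k = 16) {
  p <- cloud$positions
  n <- nrow(p)
  if (n < k + 1) stop("too few points for normal estimation")
  D <- as.matrix(stats::dist(p))
  nrm <- matrix(0, n, 3)
  nbrs <- apply(D, 1, function(row) order(row)[2:(k + 1)])
  for (i in seq_len(n)) {
    nb <- p[nbrs[, i], , drop = FALSE]
    cv <- stats::cov(nb)
    ev <- eigen(cv, symmetric = TRUE)
    nrm[i, ] <- ev$vectors[, 3]
  }
  # orientation propagation along the Euclidean MST (Prim's algorithm)
  visited <- logical(n); visited[1] <- TRUE
  dist_to_tree <- D[1, ]; parent <- rep(1L, n)
  order_visited <- integer(n); order_visited[1] <- 1L
  for (step in 2:n) {
    cand <- which(!visited)
    j <- cand[which.min(dist_to_tree[cand])]
    visited[j] <- TRUE
    order_visited[step] <- j
    if (sum(nrm[j, ] * nrm[parent[j], ]) < 0) nrm[j, ] <- -nrm[j, ]
    upd <- !visited & D[j, ] < dist_to_tree
    parent[upd] <- j
    dist_to_tree[upd] <- D[j, upd]
  }
  cen <- colMeans(p)
  outward <- mean(rowSums((p - matrix(cen, n, 3, byrow = TRUE)) * nrm))
  if (outward < 0) nrm <- -nrm
  point_cloud(p, colors = cloud$colors,
              normals = nrm / sqrt(rowSums(nrm^2)))
}
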