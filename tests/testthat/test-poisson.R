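test_that("octree refines sample-bearing nodes to the requested depth", {
  single <- point_cloud(matrix(c(0.3, -0.2, 0.1), 1))
  tree <- build_octree(single, 4)
  # a single point induces one refinement path of nested nodes
  depth_of <- function(node) {
    if (is.null(node$children)) return(node$depth)
    kids <- Filter(Negate(is.null), node$children)
    expect_length(kids, 1)
    depth_of(kids[[1]])
  }
  expect_equal(depth_of(tree$root), 4)
  with_seed_test(10, {
    cl <- point_cloud(matrix(stats::runif(3000), ncol = 3))
    tr <- build_octree(cl, 4)
    counts <- canopyscan:::octree_locate(tr, cl)
    expect_true(all(counts == 1))  # each sample in exactly one depth-4 leaf
    lv <- octree_leaves(tr)
    expect_equal(sum(lv$n_samples), 1000)
    expect_equal(unique(round(lv$width / (tr$root$width / 16), 9)), 1)
  })
  expect_error(build_octree(single, 0), "depth")
  expect_error(build_octree(point_cloud(matrix(0, 0, 3)), 4), "no samples")
})

test_that("splatting distributes unit normals with weights summing to one", {
  # node centers sit at origin + (i + 0.5) h, i.e. -1.5, -0.5, 0.5, 1.5
  grid <- list(origin = c(-2, -2, -2), h = 1, n = 4L)
  at_center <- point_cloud(matrix(c(-0.5, -0.5, -0.5), 1),
                           normals = matrix(c(0, 0, 1), 1))
  V <- splat_vector_field(at_center, grid)
  expect_equal(sum(V$vz != 0), 1)
  expect_equal(sum(V$vz), 1)
  # midpoint between two node centers: 0.5/0.5 along that axis only
  mid <- point_cloud(matrix(c(0, -0.5, -0.5), 1),
                     normals = matrix(c(1, 0, 0), 1))
  Vm <- splat_vector_field(mid, grid)
  expect_equal(sort(Vm$vx[Vm$vx != 0]), c(0.5, 0.5))
  # conservation: total splatted mass equals the number of unit normals
  sph <- sphere_cloud(500, radius = 1.2, seed = 2)
  g2 <- canopyscan:::field_grid(sph, 4, 1.3)
  Vs <- splat_vector_field(sph, g2)
  expect_equal(attr(Vs, "weight_sums"), rep(1, 500), tolerance = 1e-12)
  Vt <- splat_vector_field(sph, g2, method = "tricubic")
  expect_equal(attr(Vt, "weight_sums"), rep(1, 500), tolerance = 1e-12)
  expect_error(splat_vector_field(point_cloud(matrix(0, 1, 3)), grid),
               "normals")
})

test_that("Gauss-Seidel reproduces closed-form and direct solutions", {
  r <- gauss_seidel_solve(matrix(c(4, 1, 1, 3), 2, 2), c(1, 2), tol = 1e-12)
  expect_equal(r$x, c(1 / 11, 7 / 11), tolerance = 1e-10)
  b <- c(3, -1, 2)
  expect_equal(gauss_seidel_solve(diag(3), b)$x, b)
  expect_error(gauss_seidel_solve(matrix(c(0, 1, 1, 3), 2, 2), c(1, 2)),
               "singular diagonal")
  # oracle equivalence with a dense direct solve on random SPD systems
  with_seed_test(21, {
    for (n in c(50, 200, 500)) {
      M <- matrix(stats::rnorm(n * n), n)
      A <- crossprod(M) / n + diag(n)
      b <- stats::rnorm(n)
      gs <- gauss_seidel_solve(A, b, tol = 1e-12, max_iter = 20000)
      expect_lt(max(abs(gs$x - solve(A, b))), 1e-8)
    }
  })
  expect_warning(gauss_seidel_solve(matrix(c(4, 1, 1, 3), 2, 2), c(1, 2),
                                    tol = 1e-14, max_iter = 2),
                 "did not reach")
})

test_that("basis is the unit-integral quadratic B-spline with 3-cell support", {
  bs <- basis_spec()
  expect_equal(bs$support, 3)
  expect_equal(stats::integrate(bs$profile, -2, 2)$value, 1, tolerance = 1e-9)
  expect_equal(bs$profile(c(-1.5, 1.5, 2)), c(0, 0, 0))
  expect_equal(bs$profile(0), 0.75)
  # tables match an independent Riemann-sum quadrature
  tabs <- canopyscan:::basis_tables()
  xs <- seq(-4, 4, length.out = 40001)
  dx <- xs[2] - xs[1]
  mu0 <- sum(canopyscan:::bspline2(xs)^2) * dx
  expect_equal(tabs$mu[3], mu0, tolerance = 1e-6)
  sg1 <- sum(canopyscan:::bspline2_deriv(xs) *
               canopyscan:::bspline2_deriv(xs - 1)) * dx
  expect_equal(tabs$sigma[4], sg1, tolerance = 1e-6)
})

test_that("Poisson solve recovers a sphere with sub-cell accuracy", {
  cl <- sphere_cloud(2000, radius = 10, seed = 7)
  f4 <- solve_poisson(cl, depth = 4)
  f5 <- cached("sphere_field5", function() solve_poisson(cl, depth = 5))
  rms_err <- function(field) {
    mesh <- marching_tetrahedra(field)
    vr <- sqrt(rowSums(mesh$vertices^2))
    sqrt(mean((vr - 10)^2))
  }
  e4 <- rms_err(f4); e5 <- rms_err(f5)
  expect_lt(e5, f5$grid$h)        # within half a cell in practice
  expect_lt(e5, e4)               # finer depth, smaller error
  # flipping all normals negates phi up to solver tolerance
  cl_flip <- point_cloud(cl$positions, normals = -cl$normals)
  f_flip <- solve_poisson(cl_flip, depth = 4)
  probe <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 11, 0), c(8, -8, 2))
  expect_equal(eval_field(f_flip, probe), -eval_field(f4, probe),
               tolerance = 1e-4)
  # inside/outside separation
  expect_lt(eval_field(f5, matrix(0, 1, 3)),
            eval_field(f5, matrix(c(12.9, 0, 0), 1)) - 0.1)
})

test_that("marching tetrahedra extracts an accurate analytic sphere", {
  n <- 32
  gx <- seq(-1.3, 1.3, length.out = n + 1)
  vals <- array(0, c(n + 1, n + 1, n + 1))
  for (k in 1:(n + 1))
    vals[, , k] <- sqrt(outer(gx^2, gx^2, "+") + gx[k]^2) - 1
  h <- gx[2] - gx[1]
  mesh <- marching_tetrahedra(vals, isovalue = 0, origin = rep(-1.3, 3), h = h)
  expect_gt(nrow(mesh$faces), 1000)
  expect_lt(abs(mesh_area(mesh) - 4 * pi) / (4 * pi), 0.05)
  # every vertex sits on the zero level within interpolation tolerance
  vr <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(vr - 1)), h)
  # constant-sign field: empty mesh, not an error
  empty <- marching_tetrahedra(array(1, c(5, 5, 5)), isovalue = 0,
                               origin = c(0, 0, 0), h = 1)
  expect_equal(nrow(empty$faces), 0)
})

test_that("mesh extraction is deterministic for a fixed cloud ordering", {
  cl <- sphere_cloud(600, radius = 5, seed = 9)
  m1 <- marching_tetrahedra(solve_poisson(cl, depth = 4))
  m2 <- marching_tetrahedra(solve_poisson(cl, depth = 4))
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})

test_that("normal estimation orients a sphere's normals outward", {
  cl <- sphere_cloud(400, radius = 3, seed = 13)
  raw <- point_cloud(cl$positions)
  est <- estimate_normals(raw, k = 12)
  dots <- rowSums(est$normals * cl$normals)
  expect_gt(mean(dots > 0.9), 0.97)
})
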