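test_that("identity orientation gives the scale + half-voxel affine", {
  g <- volume_grid(array(0, c(6, 7, 8)), c(1, 1, 2))
  h <- streamline_header(c(6, 7, 8), c(1, 1, 2), "RAS")
  a <- reconcile_affine(h, g)
  expected <- rbind(c(1, 0, 0, 0.5),
                    c(0, 1, 0, 0.5),
                    c(0, 0, 2, 1.0),
                    c(0, 0, 0, 1))
  expect_equal(a$matrix, expected)
  expect_true(is.matrix(a$matrix) && all(dim(a$matrix) == c(4, 4)))
})

test_that("LPS grid vs RAS streamlines: corner voxels map correctly", {
  # 2x2x2 grid of 2 mm voxels; enumerate all 8 corner voxels through both
  # frames by brute force and compare with the reconciled matrix
  g <- volume_grid(array(0, c(2, 2, 2)), c(2, 2, 2), axis_codes = "LPS")
  h <- streamline_header(c(2, 2, 2), c(2, 2, 2), "RAS")
  a <- reconcile_affine(h, g)
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    # grid axes point L, P, S; streamline axes R, A, S. The first two axes
    # flip: streamline-frame voxel index = dims - 1 - grid index there.
    u <- c(1 - i, 1 - j, k)
    expected_point <- (u + 0.5) * c(2, 2, 2)
    got <- voxel_to_point(c(i, j, k), a)
    expect_equal(as.numeric(got), expected_point)
    expect_identical(as.integer(point_to_voxel(expected_point, a)),
                     as.integer(c(i, j, k)))
  }
})

test_that("irreconcilable dims raise an error listing both triples", {
  g <- volume_grid(array(0, c(4, 5, 6)), c(1, 1, 1))
  h <- streamline_header(c(4, 5, 7), c(1, 1, 1), "RAS")
  expect_error(reconcile_affine(h, g), "4, 5, 6.*4, 5, 7")
})

test_that("voxel size disagreement beyond 1e-3 mm is rejected", {
  g <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
  h <- streamline_header(c(4, 4, 4), c(1, 1, 1.01), "RAS")
  expect_error(reconcile_affine(h, g), "voxel sizes disagree")
})

test_that("boundary points follow the floor convention", {
  g <- volume_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
  a <- reconcile_affine(streamline_header(c(4, 4, 4), c(1, 1, 1)), g)
  expect_identical(as.integer(point_to_voxel(c(0.5, 0.5, 0.5), a)),
                   c(0L, 0L, 0L))
  # exactly on a boundary -> higher-index voxel
  expect_identical(as.integer(point_to_voxel(c(2.0, 0.5, 0.5), a)),
                   c(2L, 0L, 0L))
  # outside the grid -> NA sentinel, not an error
  expect_true(all(is.na(point_to_voxel(c(-0.1, 1, 1), a))))
  expect_true(all(is.na(point_to_voxel(c(4.0, 1, 1), a))))
})

test_that("random points agree with a brute-force box-membership oracle", {
  set.seed(42)
  vs <- c(1.1, 0.9, 2)
  dims <- c(5, 6, 4)
  g <- volume_grid(array(0, dims), vs, axis_codes = "LAS")
  h <- streamline_header(dims[c(1, 2, 3)], vs, "LAS")
  a <- reconcile_affine(h, g)
  pts <- cbind(runif(1000, 0, dims[1] * vs[1]),
               runif(1000, 0, dims[2] * vs[2]),
               runif(1000, 0, dims[3] * vs[3]))
  v <- point_to_voxel(pts, a)
  # oracle: a point belongs to voxel (i,j,k) iff it lies in its half-open box
  for (r in sample(1000, 120)) {
    hit <- NULL
    for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
      for (k in 0:(dims[3] - 1)) {
        lo <- c(i, j, k) * vs
        hi <- lo + vs
        if (all(pts[r, ] >= lo) && all(pts[r, ] < hi)) hit <- c(i, j, k)
      }
    expect_identical(as.integer(v[r, ]), as.integer(hit))
  }
})

test_that("voxel-center round trip holds for every in-bounds voxel", {
  # (grid codes, streamline codes, grid axis feeding each streamline axis)
  cases <- list(list("RAS", "RAS", c(1, 2, 3)),
                list("LPS", "RAS", c(1, 2, 3)),
                list("RAS", "ASL", c(2, 3, 1)),
                list("LAI", "RAS", c(1, 2, 3)))
  for (cs in cases) {
    dims <- c(3, 4, 5)
    vs <- c(1.09, 1.09, 2)
    g <- volume_grid(array(0, dims), vs, axis_codes = cs[[1]])
    h <- streamline_header(dims[cs[[3]]], vs[cs[[3]]], cs[[2]])
    a <- reconcile_affine(h, g)
    vox <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                                 0:(dims[3] - 1)))
    pts <- voxel_to_point(vox, a)
    back <- point_to_voxel(pts, a)
    expect_identical(unname(back),
                     matrix(as.integer(vox), ncol = 3))
  }
})

test_that("swapping argument order yields mutually inverse point maps", {
  # the same physical volume described in two frames: frame 1 = RAS order,
  # frame 2 = PRS order (first two axes swapped, y flipped)
  dims1 <- c(4, 5, 6)
  vs1 <- c(1, 1.5, 2)
  g1 <- volume_grid(array(0, dims1), vs1, axis_codes = "RAS")
  g2 <- volume_grid(array(0, dims1[c(2, 1, 3)]), vs1[c(2, 1, 3)],
                    axis_codes = "PRS")
  h1 <- streamline_header(g2$dims, g2$voxel_sizes, "PRS")
  h2 <- streamline_header(dims1, vs1, "RAS")
  m12 <- reconcile_affine(h1, g1)$matrix  # g1 voxel -> frame-2 point
  m21 <- reconcile_affine(h2, g2)$matrix  # g2 voxel -> frame-1 point
  # own-frame voxel -> point maps, to lift both to point -> point
  a1 <- reconcile_affine(streamline_header(dims1, vs1, "RAS"), g1)$matrix
  a2 <- reconcile_affine(h1, g2)$matrix
  n12 <- m12 %*% solve(a1)  # frame-1 point -> frame-2 point
  n21 <- m21 %*% solve(a2)  # frame-2 point -> frame-1 point
  expect_equal(n12 %*% n21, diag(4), tolerance = 1e-9)
  expect_equal(n21 %*% n12, diag(4), tolerance = 1e-9)
})

test_that("frame consistency: streamline frame and grid affine agree on landmarks", {
  # construct grid and header from the same world geometry (RAS world,
  # corner-origin) and check a physical landmark maps identically
  dims <- c(6, 6, 6)
  vs <- c(1, 1, 2)
  affine <- diag(c(vs, 1))
  affine[1:3, 4] <- vs / 2  # world origin at corner, center of voxel 0 at vs/2
  g <- volume_grid(array(0, dims), vs, affine = affine, axis_codes = "RAS")
  h <- streamline_header(dims, vs, "RAS")
  a <- reconcile_affine(h, g)
  vox <- rbind(c(0, 0, 0), c(3, 2, 4), c(5, 5, 5))
  world_via_grid <- apply_affine(vox, g$affine)
  # identical frames: streamline voxmm space IS this world space
  world_via_stream <- voxel_to_point(vox, a)
  expect_equal(world_via_grid, world_via_stream, tolerance = 1e-6)
})

test_that("non-invertible or inconsistent affines are rejected", {
  af <- diag(c(1, 1, 0, 1))
  expect_error(volume_grid(array(0, c(2, 2, 2)), c(1, 1, 1), affine = af),
               "invertible|column norms")
  af2 <- diag(c(1, 1, 3, 1))  # claims 3 mm but voxel_sizes say 1
  expect_error(volume_grid(array(0, c(2, 2, 2)), c(1, 1, 1), affine = af2),
               "column norms")
})
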