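test_that("scale ladder follows the log-spaced definition", {
  lad <- scale_ladder(14)
  expect_identical(length(lad$scales), 15L)
  expect_equal(lad$scales[1], 10^-0.5)
  expect_identical(lad$display[1], "0.32")
  expect_identical(lad$display[2], "0.37")
  expect_identical(lad$display[15], "3.02")
  expect_identical(lad$display[12], "1.86")
  expect_true(all(diff(lad$scales) > 0))
  expect_error(scale_ladder(-1), class = "cs_validation_error")
})

test_that("voxelized shell volume matches the divergence-theorem oracle", {
  pair <- sphere_pair_small()  # R = 10, t = 2
  seg <- voxelize_pair(pair, 0.5)
  v_vox <- sum(seg$grid == 1L) * 0.5^3
  v_mesh <- mesh_volume(pair$pial) - mesh_volume(pair$white)
  expect_lt(abs(v_vox / v_mesh - 1), 0.05)
  expect_gt(sum(seg$grid == 2L), 0)
})

test_that("degenerate pairs are handled: empty shell, oversized lambda", {
  pair <- sphere_pair_small()
  same <- structure(list(pial = pair$pial, white = pair$pial,
                         labels = NULL, hemisphere_id = "lh"),
                    class = "cortical_surface_pair")
  seg <- voxelize_pair(same, 1)
  expect_identical(sum(seg$grid == 1L), 0L)  # no GM left
  expect_error(voxelize_pair(pair, 50), class = "cs_degenerate_grid_error")
})

test_that("grid keeps a background margin around all tissue", {
  seg <- voxelize_pair(sphere_pair_small(), 0.8)
  g <- seg$grid
  d <- dim(g)
  expect_true(all(g[c(1, d[1]), , ] == 0L))
  expect_true(all(g[, c(1, d[2]), ] == 0L))
  expect_true(all(g[, , c(1, d[3])] == 0L))
})

test_that("scanline classification agrees with the winding number", {
  pair <- sphere_pair_small()
  seg <- voxelize_pair(pair, 1)
  set.seed(2)
  idx <- sample(length(seg$grid), 150)
  ai <- arrayInd(idx, dim(seg$grid))
  centers <- sweep((ai - 0.5) * seg$lambda, 2, seg$origin, "+")
  in_p <- points_in_mesh(centers, pair$pial)
  in_w <- points_in_mesh(centers, pair$white)
  expected <- ifelse(in_w, 2L, ifelse(in_p, 1L, 0L))
  expect_identical(as.integer(seg$grid[idx]), expected)
})

test_that("a single voxel without smoothing yields the midpoint octahedron", {
  g <- array(0L, c(3, 3, 3)); g[2, 2, 2] <- 1L
  seg <- cortexscales:::voxel_segmentation(g, c(0, 0, 0), 1)
  oct <- extract_isosurface(seg, "pial", smooth = FALSE)
  expect_identical(nrow(oct$faces), 8L)
  expect_equal(mesh_area(oct), sqrt(3), tolerance = 1e-12)
  expect_true(mesh_is_closed(oct))
  expect_gt(mesh_volume(oct), 0)
})

test_that("isosurface area of a voxel cube converges to the analytic area", {
  n <- 20
  g <- array(0L, c(n + 2, n + 2, n + 2))
  g[2:(n + 1), 2:(n + 1), 2:(n + 1)] <- 1L
  seg <- cortexscales:::voxel_segmentation(g, c(0, 0, 0), 1)
  cube <- extract_isosurface(seg, "pial", smooth = FALSE)
  expect_lt(abs(mesh_area(cube) / (6 * n^2) - 1), 0.05)
  expect_true(mesh_is_closed(cube))
})

test_that("extracted isosurfaces are closed and outward for both tissues", {
  seg <- voxelize_pair(sphere_pair_small(), 0.7)
  for (tissue in c("pial", "white")) {
    m <- extract_isosurface(seg, tissue)
    expect_true(mesh_is_closed(m))
    expect_gt(mesh_volume(m), 0)
  }
  empty <- cortexscales:::voxel_segmentation(
    array(c(0L, 1L, rep(0L, 25)), c(3, 3, 3)), c(0, 0, 0), 1)
  expect_error(extract_isosurface(empty, "white"),
               class = "cs_validation_error")
})

test_that("coarse-grained sphere area converges to 4 pi R^2", {
  # refinement consistency at lambda = R/60
  pair <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 30, a = 0, m = 0, t = 2.5, subdivisions = 4))
  seg <- voxelize_pair(pair, 0.5)
  cg <- extract_isosurface(seg, "pial")
  expect_lt(abs(mesh_area(cg) / (4 * pi * 900) - 1), 0.03)
})

test_that("coarse-graining removes folds below the cut-off and keeps them above", {
  # fold arc-wavelength w = 2 pi R / m = 4.71 mm
  pair <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 30, a = 0.5, m = 40, t = 2.5,
                          subdivisions = 6))
  native <- mesh_area(pair$pial)
  w <- 2 * pi * 30 / 40
  seg_hi <- voxelize_pair(pair, w)
  a_coarse <- mesh_area(extract_isosurface(seg_hi, "pial"))
  expect_lt(abs(a_coarse / (4 * pi * 900) - 1), 0.10)  # folds removed
  seg_lo <- voxelize_pair(pair, w / 15)
  a_fine <- mesh_area(extract_isosurface(seg_lo, "pial"))
  expect_lt(abs(a_fine / native - 1), 0.10)            # folds retained
})

test_that("closing is the identity on a convex ball and for tiny elements", {
  seg <- voxelize_pair(sphere_pair_small(), 0.5)
  cl <- close_mask(seg, 15)
  expect_identical(sum(cl$grid != 0L), sum(seg$grid != 0L))
  cl2 <- close_mask(seg, 0.4)  # diameter < lambda
  expect_identical(cl2, seg)
  expect_error(close_mask(seg, -1), class = "cs_validation_error")
})

test_that("closing bridges a sulcus-like gap between slabs", {
  g <- array(0L, c(30, 30, 20))
  g[5:25, 5:25, 6:7] <- 1L   # slab 1
  g[5:25, 5:25, 13:14] <- 1L # slab 2, 5 voxels away (lambda = 1 mm)
  seg <- cortexscales:::voxel_segmentation(g, c(0, 0, 0), 1)
  cl <- close_mask(seg, 15)
  pad <- (dim(cl$grid) - dim(g)) %/% 2
  expect_true(all(cl$grid[pad[1] + 15, pad[2] + 15, pad[3] + 8:12] != 0L))
  expect_gte(sum(cl$grid != 0L), sum(g != 0L))  # closing is extensive
})

test_that("convex hull reproduces analytic hulls and bounds folded surfaces", {
  hc <- convex_hull_surface(cube_mesh(2))
  expect_equal(mesh_area(hc), 24, tolerance = 1e-12)
  expect_equal(mesh_volume(hc), 8, tolerance = 1e-12)
  expect_true(mesh_is_closed(hc))

  ic <- icosphere(4)
  hi <- convex_hull_surface(ic)
  expect_lt(abs(mesh_area(hi) / mesh_area(ic) - 1), 0.005)

  pair <- folded_pair()
  hf <- convex_hull_surface(pair$pial)
  expect_lt(mesh_area(hf), mesh_area(pair$pial))

  flat <- triangle_mesh(cbind(rnorm(10), rnorm(10), 0),
                        matrix(c(1L, 2L, 3L), 1), validate = FALSE)
  expect_error(convex_hull_surface(flat), class = "cs_degenerate_error")
})
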