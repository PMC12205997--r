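test_that("mesh area and volume match analytic solids", {
  cube <- cube_mesh()
  expect_equal(mesh_area(cube), 6, tolerance = 1e-12)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  flipped <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), -1, tolerance = 1e-12)

  ic <- icosphere(4)
  expect_lt(abs(mesh_area(ic) / (4 * pi) - 1), 0.005)
  ic2 <- triangle_mesh(2 * ic$vertices, ic$faces)
  expect_lt(abs(mesh_volume(ic2) / (4 / 3 * pi * 8) - 1), 0.01)

  empty <- triangle_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3))
  expect_identical(mesh_area(empty), 0)
  open <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_error(mesh_volume(open), class = "cs_validation_error")
})

test_that("hemisphere metrics implement the ratio-thickness definition", {
  g <- array(0L, c(6, 6, 6)); g[2:5, 2:5, 2:5] <- 1L
  seg <- cortexscales:::voxel_segmentation(g, c(0, 0, 0), 1)
  fake_pial <- cube_mesh(5)  # area 150
  fake_hull <- cube_mesh(5)
  hm <- hemisphere_metrics(seg, fake_pial, fake_hull)
  expect_equal(hm$V_GM, 64)
  expect_equal(hm$T, 64 / 150)

  # concentric spheres at lambda = 0.5: T within 10% of the 2.5 mm offset
  pair <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 30, a = 0, m = 0, t = 2.5, subdivisions = 4))
  seg2 <- voxelize_pair(pair, 0.5)
  pial_cg <- extract_isosurface(seg2, "pial")
  hm2 <- hemisphere_metrics(seg2, pial_cg, convex_hull_surface(pial_cg))
  expect_lt(abs(hm2$T / 2.5 - 1), 0.10)
})

test_that("ratio and distance thickness agree on thin smooth shells", {
  pair <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 10, a = 0, m = 0, t = 1, subdivisions = 3))
  seg <- voxelize_pair(pair, 0.4)
  pial_cg <- extract_isosurface(seg, "pial")
  hm <- hemisphere_metrics(seg, pial_cg, pial_cg)
  lt <- lobe_thickness(pair$pial, pair$white,
                       vertex_labels(rep(1L, nrow(pair$pial$vertices)),
                                     c(`1` = "all")))
  expect_lt(abs(hm$T / lt$thickness[["all"]] - 1), 0.15)
})

test_that("label transfer is nearest-vertex with deterministic ties", {
  pair <- labelled_sphere_pair()
  same <- transfer_labels(pair$pial, pair$pial, pair$labels)
  expect_identical(same$labels, pair$labels$labels)

  const <- vertex_labels(rep(7L, nrow(pair$pial$vertices)), c(`7` = "x"))
  seg <- voxelize_pair(pair, 1)
  cg <- extract_isosurface(seg, "pial")
  tr <- transfer_labels(cg, pair$pial, const)
  expect_true(all(tr$labels == 7L))

  # transferred sector boundaries stay within ~2 lambda of the sector
  # planes (x = 0 and y = 0), measured as Euclidean violation depth
  tr2 <- transfer_labels(cg, pair$pial, pair$labels)
  v <- cg$vertices
  # each azimuthal quadrant is an intersection of two half-spaces
  halfspace <- list(`1` = cbind(v[, 1], v[, 2]),
                    `2` = cbind(-v[, 1], v[, 2]),
                    `3` = cbind(-v[, 1], -v[, 2]),
                    `4` = cbind(v[, 1], -v[, 2]))
  tol <- 2 * seg$lambda
  for (code in 1:4) {
    sel <- tr2$labels == code
    if (!any(sel)) next
    viol <- pmax(0, -halfspace[[as.character(code)]][sel, 1],
                 -halfspace[[as.character(code)]][sel, 2])
    expect_lt(max(viol), tol + 1e-9)
  }
})

test_that("lobe areas partition the mesh area exactly", {
  pair <- labelled_sphere_pair()
  ar <- lobe_areas(pair$pial, pair$labels)
  expect_equal(sum(ar), mesh_area(pair$pial), tolerance = 1e-12)

  const <- vertex_labels(rep(1L, nrow(pair$pial$vertices)), c(`1` = "all"))
  ar1 <- lobe_areas(pair$pial, const)
  expect_identical(names(ar1), "all")
  expect_equal(unname(ar1), mesh_area(pair$pial))

  # hemisphere split of an icosphere: each half within 2% of 2 pi
  ic <- icosphere(5)
  half <- vertex_labels(ifelse(ic$vertices[, 3] >= 0, 1L, 2L),
                        c(`1` = "north", `2` = "south"))
  ah <- lobe_areas(ic, half)
  expect_lt(abs(ah[["north"]] / (2 * pi) - 1), 0.02)
  expect_lt(abs(ah[["south"]] / (2 * pi) - 1), 0.02)
})

test_that("vertex-to-white distances behave like point-to-set minima", {
  pair <- labelled_sphere_pair()
  lt <- lobe_thickness(pair$pial, pair$white, pair$labels)
  expect_lt(max(abs(lt$thickness / 2 - 1), na.rm = TRUE), 0.02)

  # point-to-triangle never exceeds point-to-nearest-vertex
  d_tri <- lt$vertex_distance
  nearest <- cortexscales:::nearest_vertex_idx(pair$pial$vertices,
                                               pair$white$vertices) + 1L
  d_vert <- sqrt(rowSums((pair$pial$vertices -
                          pair$white$vertices[nearest, ])^2))
  expect_true(all(d_tri <= d_vert + 1e-9))

  # a pial vertex lying on a white face has distance zero
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                             c(0, 0, 2)),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3),
                             c(2, 3, 4)))
  pt <- matrix(c(0.5, 0.5, 0), 1)
  d0 <- cortexscales:::point_to_mesh_distance(pt, tri$vertices,
                                              tri$faces - 1L)
  expect_equal(as.numeric(d0), 0, tolerance = 1e-12)
})

test_that("insula redistribution is proportional and conservative", {
  raw <- data.frame(
    region = c("frontal", "parietal", "temporal", "occipital", "insula"),
    A_t = c(50, 30, 20, 40, 10),
    T = c(2.0, 2.2, 2.4, 2.6, 3.0))
  out <- redistribute_insula(raw)
  expect_equal(out$A_t[out$region == "frontal"], 55)
  expect_equal(out$A_t[out$region == "parietal"], 33)
  expect_equal(out$A_t[out$region == "temporal"], 22)
  expect_equal(out$A_t[out$region == "occipital"], 40)
  expect_equal(sum(out$A_t), sum(raw$A_t), tolerance = 1e-12)
  # area-weighted mean thickness of the recipient set is conserved
  expect_equal(sum(out$A_t * out$T), sum(raw$A_t * raw$T),
               tolerance = 1e-12)

  raw0 <- raw; raw0$A_t[5] <- 0
  out0 <- redistribute_insula(raw0)
  expect_equal(out0$A_t, raw$A_t[1:4])
  expect_equal(out0$T, raw$T[1:4])

  bad <- raw; bad$A_t[1:3] <- 0
  expect_error(redistribute_insula(bad), class = "cs_validation_error")
})

test_that("scale sweep emits the declared row structure", {
  pair <- labelled_sphere_pair()
  lad <- scale_ladder(2)
  tab <- run_scale_sweep(pair, lad, sweep_config(), subject_id = "s1")
  hemi <- tab[tab$structure == "hemisphere" & tab$metric == "A_t", ]
  expect_identical(nrow(hemi), 4L)  # 3 ladder scales + native
  expect_identical(hemi$lambda[1], "native")
  expect_true(all(c("frontal", "parietal", "temporal", "occipital")
                  %in% tab$structure))
  expect_false("insula" %in% tab$structure)

  # post-redistribution lobe areas sum exactly to hemisphere A_t
  for (lam in unique(tab$lambda)) {
    lob <- tab[tab$lambda == lam & tab$metric == "A_t" &
               tab$structure != "hemisphere", ]
    h <- tab$value[tab$lambda == lam & tab$metric == "A_t" &
                   tab$structure == "hemisphere"]
    expect_equal(sum(lob$value), h, tolerance = 1e-9)
  }

  # native A_t exceeds every coarse-grained A_t for the smooth pair too
  expect_true(all(hemi$value[1] >= hemi$value[-1] * 0.95))

  tf <- tempfile(fileext = ".csv")
  write_multiscale_table(tab, tf)
  tab2 <- read_multiscale_table(tf)
  expect_equal(tab2$value, tab$value, tolerance = 0)
  expect_identical(tab2$lambda, tab$lambda)
})

test_that("sweep output is invariant to vertex re-indexing and lambda shifts", {
  pair <- sphere_pair_small()
  lad <- scale_ladder(0)
  base <- run_scale_sweep(pair, lad, sweep_config(lobes = FALSE))

  # permute vertices (faces remapped accordingly)
  perm_mesh <- function(m, p) {
    inv <- integer(length(p)); inv[p] <- seq_along(p)
    triangle_mesh(m$vertices[p, ], matrix(inv[m$faces], ncol = 3))
  }
  set.seed(9)
  p1 <- sample(nrow(pair$pial$vertices))
  pairp <- structure(list(pial = perm_mesh(pair$pial, p1),
                          white = perm_mesh(pair$white, p1),
                          labels = NULL, hemisphere_id = "lh"),
                     class = "cortical_surface_pair")
  perm <- run_scale_sweep(pairp, lad, sweep_config(lobes = FALSE))
  expect_equal(perm$value, base$value, tolerance = 1e-9)

  # rigid translation by a multiple of lambda
  lam <- lad$scales[1]
  shift <- function(m) triangle_mesh(sweep(m$vertices, 2,
                                           c(2, -3, 5) * lam, "+"), m$faces)
  pairs <- structure(list(pial = shift(pair$pial), white = shift(pair$white),
                          labels = NULL, hemisphere_id = "lh"),
                     class = "cortical_surface_pair")
  trans <- run_scale_sweep(pairs, lad, sweep_config(lobes = FALSE))
  expect_equal(trans$value, base$value, tolerance = 1e-6)
})
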