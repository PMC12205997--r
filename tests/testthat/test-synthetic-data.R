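test_that("smooth-sphere pair matches analytic area and thickness", {
  pair <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 30, a = 0, m = 0, t = 2.5, subdivisions = 4))
  expect_lt(abs(mesh_area(pair$pial) / (4 * pi * 30^2) - 1), 0.01)
  expect_lt(abs(mesh_area(pair$white) / (4 * pi * 27.5^2) - 1), 0.01)
  d <- lobe_thickness(pair$pial, pair$white,
                      vertex_labels(rep(1L, nrow(pair$pial$vertices)),
                                    c(`1` = "all")))
  expect_lt(max(abs(d$vertex_distance / 2.5 - 1)), 0.02)
})

test_that("generated pairs pass the mesh audit (closed, oriented, nested)", {
  for (pair in list(sphere_pair_small(), folded_pair())) {
    expect_true(mesh_is_closed(pair$pial))
    expect_true(mesh_is_closed(pair$white))
    expect_gt(mesh_volume(pair$pial), 0)  # outward orientation
    expect_gt(mesh_volume(pair$white), 0)
    # white strictly inside pial (winding number on a vertex subsample)
    idx <- seq(1, nrow(pair$white$vertices), length.out = 50)
    expect_true(all(points_in_mesh(pair$white$vertices[idx, ], pair$pial)))
  }
})

test_that("folding strictly increases pial area beyond the smooth bound", {
  pair <- folded_pair()
  expect_gt(mesh_area(pair$pial), 4 * pi * 30^2)
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_cortex_spec(R = 10, a = 11),
               class = "cs_validation_error")
  expect_error(synthetic_cortex_spec(R = 10, a = 2, t = 9),
               class = "cs_validation_error")
  expect_error(synthetic_cortex_spec(t = 0), class = "cs_validation_error")
})

test_that("quadrant labels partition the pial vertices into 5 regions", {
  pair <- sphere_pair_small()
  lab <- make_quadrant_labels(pair)
  counts <- table(lab$labels)
  expect_identical(sort(as.integer(names(counts))), 1:5)
  expect_identical(sum(counts), nrow(pair$pial$vertices))
  expect_lt(counts[["5"]] / sum(counts), 0.10)  # small insula

  # zero cap radius: insula empty, 4 regions remain
  lab0 <- make_quadrant_labels(pair, insula_angle = 0)
  expect_false(5L %in% lab0$labels)
  expect_identical(length(table(lab0$labels)), 4L)

  # sector boundaries: non-insular vertices lie in their azimuthal quadrant
  u <- pair$pial$vertices / sqrt(rowSums(pair$pial$vertices^2))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  sector <- findInterval(phi, c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
                         rightmost.closed = TRUE)
  sel <- lab$labels != 5L
  expect_identical(lab$labels[sel], sector[sel])
})

test_that("cohort generation is deterministic and respects the spec", {
  spec <- cohort_preset(seed = 3)
  co1 <- make_cohort(spec)
  co2 <- make_cohort(spec)
  expect_identical(co1, co2)
  expect_identical(nrow(co1), 800L)
  expect_true(all(co1$age >= 6 & co1$age <= 88))
  expect_true(all(!is.na(as.matrix(co1[, -1]))))
  expect_gte(length(unique(co1$site)), 2L)
})

test_that("zero-noise limit reproduces trajectory plus offsets exactly", {
  traj <- list(m1 = function(a) 10 + a)
  spec <- cohort_spec(n = 50, trajectories = traj,
                      site_offsets = list(m1 = c(siteA = 0, siteB = 2)),
                      sex_offsets = list(m1 = c(f = -1, m = 1)),
                      noise_sd = c(m1 = 1e-12), seed = 5)
  co <- make_cohort(spec)
  expected <- 10 + co$age + ifelse(co$site == "siteB", 2, 0) +
    ifelse(co$sex == "m", 1, -1)
  expect_equal(co$m1, expected, tolerance = 1e-9)
})

test_that("default cohort shows the opposite-sign age correlations", {
  co <- lifespan_cohort()
  expect_lt(cor(co[["At@native"]], co$age), 0)
  expect_gt(cor(co[["At@1.86"]], co$age), 0)
})

test_that("cohort CSV round-trips through the declared header convention", {
  co <- head(lifespan_cohort(), 20)
  tf <- tempfile(fileext = ".csv")
  write_cohort_csv(co, tf)
  co2 <- read_cohort_csv(tf)
  expect_identical(names(co2), names(co))
  expect_equal(co2[["At@1.86"]], co[["At@1.86"]], tolerance = 1e-12)
})
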