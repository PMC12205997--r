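# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# concentric-sphere pair, R = 10 mm, t = 2 mm: cheap geometric oracle
sphere_pair_small <- function() fixture("sphere_small", function() {
  make_folded_sphere_pair(
    synthetic_cortex_spec(R = 10, a = 0, m = 0, t = 2, subdivisions = 3))
})

# folded pair matching the headline phantom (R = 30, a = 3, m = 12)
folded_pair <- function() fixture("folded", function() {
  p <- make_folded_sphere_pair(
    synthetic_cortex_spec(R = 30, a = 3, m = 12, t = 2.5, subdivisions = 4))
  p$labels <- make_quadrant_labels(p)
  p
})

# labelled concentric pair for lobe metrics
labelled_sphere_pair <- function() fixture("sphere_lab", function() {
  p <- sphere_pair_small()
  p$labels <- make_quadrant_labels(p)
  p
})

# default synthetic cohort
lifespan_cohort <- function() fixture("cohort", function() {
  make_cohort(cohort_preset(seed = 101))
})

# a tiny valid closed mesh: regular tetrahedron (outward-oriented)
tetra_mesh <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# unit cube mesh (12 triangles, outward-oriented)
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = side
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = side
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = side
  triangle_mesh(v, f)
}

# random closed mesh via hull of a random point cloud
random_closed_mesh <- function(n = 40) {
  pts <- matrix(rnorm(3 * n), ncol = 3)
  convex_hull_surface(triangle_mesh(pts, matrix(c(1L, 2L, 3L), 1),
                                    validate = FALSE))
}
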