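#' Icosphere
#'
#' Unit sphere triangulation by repeated loop subdivision of an
#' icosahedron with midpoint reprojection. Closed and outward-oriented by
#' construction; subdivision level s gives `10*4^s + 2` vertices.
#'
#' @param subdivisions non-negative integer.
#' @return a [triangle_mesh()] on the unit sphere.
#' @export
icosphere <- function(subdivisions = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint id per undirected edge
    ea <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    eb <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
    key <- (ea - 1) * as.double(nv) + eb
    uk <- unique(as.vector(key))
    mid_id <- match(key, uk) + nv
    ua <- floor((uk - 1) / nv) + 1
    ub <- (uk - 1) %% nv + 1
    mids <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- matrix(mid_id, ncol = 3)  # midpoints of edges 12, 23, 31
    f <- rbind(
      cbind(f[, 1], m12[, 1], m12[, 3]),
      cbind(f[, 2], m12[, 2], m12[, 1]),
      cbind(f[, 3], m12[, 3], m12[, 2]),
      m12)
  }
  triangle_mesh(v, f)
}

#' Synthetic folded-cortex specification
#'
#' Parameters of the folded-sphere phantom: a sphere of radius `R` with a
#' separable sinusoidal radial perturbation of amplitude `a` and angular
#' degree `m`, and a white surface obtained by a radial inward offset of
#' thickness `t`. With `m > 0` the dominant fold arc-wavelength is about
#' `2*pi*R/m`, the single knob controlling which folding features a given
#' coarse-graining scale removes.
#'
#' @param R base radius (mm), `R > a`.
#' @param a fold amplitude (mm), `a >= 0`.
#' @param m integer angular frequency of the perturbation.
#' @param t cortical thickness (mm), `0 < t < R - a`.
#' @param subdivisions icosphere subdivision level.
#' @param seed recorded in the generated pair's metadata.
#' @export
synthetic_cortex_spec <- function(R = 30, a = 0, m = 0, t = 2.5,
                                  subdivisions = 4, seed = 1L) {
  if (!(R > a && a >= 0))
    cs_stop("need R > a >= 0", "cs_validation_error")
  if (!(t > 0 && t < R - a))
    cs_stop("need 0 < t < R - a", "cs_validation_error")
  if (m < 0 || m != round(m))
    cs_stop("m must be a non-negative integer", "cs_validation_error")
  structure(list(R = R, a = a, m = as.integer(m), t = t,
                 subdivisions = as.integer(subdivisions),
                 seed = as.integer(seed)),
            class = "synthetic_cortex_spec")
}

#' Generate a folded pial/white surface pair
#'
#' Triangulates the surface `r(theta, phi) = R + a sin(m theta) sin(m phi)`
#' over a subdivided icosahedron (pial) and the same surface with radius
#' reduced by `t` along the radial direction (white). Both are closed and
#' outward-oriented; the radial offset construction makes the pial-to-white
#' distance equal to `t` along each ray, which serves as the analytic
#' thickness oracle.
#'
#' @param spec a [synthetic_cortex_spec()].
#' @param hemisphere_id label stored with the pair.
#' @return object of class `cortical_surface_pair` with elements `pial`,
#'   `white`, `labels` (NULL until assigned), `hemisphere_id`, `spec`.
#' @export
make_folded_sphere_pair <- function(spec, hemisphere_id = "lh") {
  if (!inherits(spec, "synthetic_cortex_spec"))
    cs_stop("spec must be a synthetic_cortex_spec", "cs_validation_error")
  base <- icosphere(spec$subdivisions)
  u <- base$vertices
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  r_p <- spec$R + spec$a * sin(spec$m * theta) * sin(spec$m * phi)
  pial <- triangle_mesh(u * r_p, base$faces)
  white <- triangle_mesh(u * (r_p - spec$t), base$faces)
  structure(list(pial = pial, white = white, labels = NULL,
                 hemisphere_id = hemisphere_id, spec = spec),
            class = "cortical_surface_pair")
}

#' @export
print.cortical_surface_pair <- function(x, ...) {
  cat(sprintf(
    "cortical_surface_pair [%s]: pial %d vertices, white %d vertices%s\n",
    x$hemisphere_id, nrow(x$pial$vertices), nrow(x$white$vertices),
    if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Quadrant lobe labels for a synthetic pair
#'
#' Assigns four lobe-like sectors (frontal, parietal, temporal, occipital)
#' by azimuthal quadrant (octants merged across the equator) plus a small
#' circular insula cap on the equator inside the frontal sector, mirroring
#' the topology of a lobar parcellation: four large connected regions and
#' one small region whose metrics get redistributed.
#'
#' @param pair a `cortical_surface_pair`.
#' @param insula_angle angular radius of the insula cap in degrees
#'   (default 25; 0 gives an empty insula).
#' @return a [vertex_labels()] on the pial mesh.
#' @export
make_quadrant_labels <- function(pair, insula_angle = 25) {
  u <- pair$pial$vertices
  u <- u / sqrt(rowSums(u^2))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  code <- findInterval(phi, c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
                       rightmost.closed = TRUE)
  cap_dir <- c(cos(pi / 4), sin(pi / 4), 0)  # equator, frontal sector
  ang <- acos(pmin(1, pmax(-1, u %*% cap_dir)))
  code[ang < insula_angle * pi / 180] <- 5L
  vertex_labels(code, c(`1` = "frontal", `2` = "parietal",
                        `3` = "temporal", `4` = "occipital",
                        `5` = "insula"))
}
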