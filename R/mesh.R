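#' Triangle mesh
#'
#' Construct a triangle mesh from a vertex coordinate matrix and a face
#' index matrix. Meshes are the geometric currency of the package: input
#' surface reconstructions, coarse-grained isosurfaces, convex hulls and
#' exposed surfaces are all `triangle_mesh` objects. Face indices are
#' 1-based inside R and converted to the 0-based convention of the on-disk
#' formats at the I/O boundary.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param validate check index ranges and degenerate faces.
#' @return an object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    cs_stop("vertices must have 3 columns", "cs_validation_error")
  if (nrow(faces) > 0L && ncol(faces) != 3L)
    cs_stop("faces must have 3 columns", "cs_validation_error")
  if (nrow(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > n)
      cs_stop("face index out of range", "cs_validation_error")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      cs_stop("face repeats a vertex index", "cs_validation_error")
  }
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Closedness and orientation audit
#'
#' A mesh is closed and consistently oriented when every directed edge
#' occurs exactly once and every undirected edge exactly twice (each edge
#' is traversed once in each direction by its two incident faces).
#'
#' @param mesh a `triangle_mesh`.
#' @return `TRUE`/`FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  n <- nrow(mesh$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  dir_key <- (a - 1) * as.double(n) + (b - 1)
  if (anyDuplicated(dir_key) > 0L) return(FALSE)
  rev_key <- (b - 1) * as.double(n) + (a - 1)
  all(dir_key %in% rev_key)
}

assert_closed <- function(mesh, what = "mesh") {
  if (!mesh_is_closed(mesh))
    cs_stop(sprintf("%s is not a closed, consistently oriented mesh", what),
            "cs_validation_error")
  invisible(mesh)
}

#' Point-in-mesh classification
#'
#' Classify points as inside/outside a closed mesh, either by scanline
#' ray-casting parity (fast; used by the voxelizer) or by the generalized
#' winding number (robust reference; used as cross-check in the tests).
#'
#' @param points numeric matrix of query points (rows).
#' @param mesh a closed `triangle_mesh`.
#' @param method `"winding"` or `"raycast"`.
#' @return logical vector.
#' @export
points_in_mesh <- function(points, mesh, method = c("winding", "raycast")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  f0 <- mesh$faces - 1L
  if (method == "winding") {
    w <- winding_number(points, mesh$vertices, f0)
    return(abs(w) > 0.5)
  }
  # raycast path reuses the grid classifier one point at a time via a
  # degenerate 1x1x1 grid around each point
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    lam <- 1e-3
    inside_mask_raycast(mesh$vertices, f0, p - lam / 2, lam, c(1L, 1L, 1L))[1]
  }, logical(1))
}
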