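#' Scale ladder
#'
#' The coarse-graining scales: `lambda_k = 10^(-0.5 + 0.07 k)` for
#' `k = 0..k_max`. With `k_max = 14` the ladder runs from 0.32 mm to
#' 3.02 mm (2-decimal display rounding); the display value 1.86 mm is
#' ladder index k = 11. The logarithmic spacing samples small scales more
#' densely, where surface reconstructions change fastest.
#'
#' @param k_max largest ladder index (>= 0).
#' @return object of class `scale_ladder` with elements `scales`
#'   (numeric, mm), `display` (2-dp labels) and `k_max`.
#' @export
scale_ladder <- function(k_max = 14) {
  if (length(k_max) != 1 || is.na(k_max) || k_max < 0 || k_max != round(k_max))
    cs_stop("k_max must be a non-negative integer", "cs_validation_error")
  k <- 0:k_max
  lam <- 10^(-0.5 + 0.07 * k)
  structure(list(scales = lam,
                 display = sprintf("%.2f", lam),
                 k_max = as.integer(k_max)),
            class = "scale_ladder")
}

#' @export
print.scale_ladder <- function(x, ...) {
  cat(sprintf("scale_ladder: k = 0..%d, lambda = %s mm\n", x$k_max,
              paste(x$display, collapse = ", ")))
  invisible(x)
}

# voxel label codes
VOX_BG <- 0L
VOX_GM <- 1L
VOX_WM <- 2L

voxel_segmentation <- function(grid, origin, lambda) {
  structure(list(grid = grid, origin = origin, lambda = lambda,
                 dims = dim(grid)),
            class = "voxel_segmentation")
}

#' @export
print.voxel_segmentation <- function(x, ...) {
  cat(sprintf(
    "voxel_segmentation: %s grid, lambda = %.4g mm, %d GM / %d WM voxels\n",
    paste(x$dims, collapse = "x"), x$lambda,
    sum(x$grid == VOX_GM), sum(x$grid == VOX_WM)))
  invisible(x)
}

#' Voxelize a surface pair at scale lambda
#'
#' Fills the closed pial/white meshes with voxels of side length `lambda`:
#' a voxel is WM if its center lies inside the white mesh, GM if inside
#' the pial mesh and not WM, else background. The grid is axis-aligned to
#' the pial bounding box expanded by a one-voxel margin, with the origin
#' snapped down to a multiple of `lambda` so the placement is
#' deterministic; a user-supplied origin overrides the snapping. The
#' center-in-mesh test is scanline ray-casting parity (cross-checked
#' against the generalized winding number in the test-suite).
#'
#' @param pair a `cortical_surface_pair`.
#' @param lambda voxel side length (mm).
#' @param origin optional fixed grid origin (corner of voxel `(0,0,0)`).
#' @return a `voxel_segmentation`.
#' @export
voxelize_pair <- function(pair, lambda, origin = NULL) {
  if (lambda <= 0) cs_stop("lambda must be > 0", "cs_validation_error")
  assert_closed(pair$pial, "pial surface")
  assert_closed(pair$white, "white surface")
  bb_min <- apply(pair$pial$vertices, 2, min)
  bb_max <- apply(pair$pial$vertices, 2, max)
  if (any(bb_max - bb_min < lambda))
    cs_stop("lambda exceeds the mesh bounding box (degenerate grid)",
            "cs_degenerate_grid_error")
  if (is.null(origin)) origin <- floor((bb_min - lambda) / lambda) * lambda
  dims <- as.integer(ceiling((bb_max + lambda - origin) / lambda))
  in_p <- inside_mask_raycast(pair$pial$vertices, pair$pial$faces - 1L,
                              origin, lambda, dims)
  in_w <- inside_mask_raycast(pair$white$vertices, pair$white$faces - 1L,
                              origin, lambda, dims)
  grid <- array(VOX_BG, dims)
  grid[in_w] <- VOX_WM
  grid[in_p & !in_w] <- VOX_GM
  voxel_segmentation(grid, origin, lambda)
}

#' Extract a coarse-grained isosurface
#'
#' Re-renders a tissue mask of the segmentation as a triangle mesh: the
#' binary indicator (GM-union-WM for the coarse-grained pial, WM for the
#' coarse-grained white) is zero-padded, optionally pre-smoothed with the
#' conventional 3x3x3 box filter, and contoured at iso-level 0.5 with
#' linear interpolation along cell edges. The extraction is watertight by
#' construction (face-consistent polygon tracing) and outward-oriented.
#'
#' Pre-smoothing matters quantitatively: contouring the raw binary
#' indicator yields edge-midpoint facets whose total area overestimates a
#' smooth surface by ~8% at any resolution, while the box-filtered field
#' converges to the true area. `smooth = FALSE` gives the literal binary
#' behaviour (a single voxel then yields the area-`sqrt(3)` octahedron).
#'
#' @param seg a `voxel_segmentation`.
#' @param tissue `"pial"` (GM union WM) or `"white"` (WM only).
#' @param smooth apply the 3^3 box pre-filter (default TRUE).
#' @return a [triangle_mesh()] in mm coordinates (voxel center of index
#'   `i` maps to `origin + (i + 0.5) * lambda`).
#' @export
extract_isosurface <- function(seg, tissue = c("pial", "white"),
                               smooth = TRUE) {
  tissue <- match.arg(tissue)
  mask <- if (tissue == "pial") seg$grid != VOX_BG else seg$grid == VOX_WM
  if (!any(mask))
    cs_stop(sprintf("selected tissue '%s' is empty", tissue),
            "cs_validation_error")
  pad <- 2L
  dims <- dim(mask) + 2L * pad
  field <- array(0, dims)
  field[pad + seq_len(dim(mask)[1]),
        pad + seq_len(dim(mask)[2]),
        pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  if (smooth)
    field <- array(box3_filter(as.numeric(field), dims), dims)
  origin <- seg$origin - pad * seg$lambda
  res <- polygon_trace_isosurface(as.numeric(field), dims, 0.5,
                                  origin, seg$lambda)
  triangle_mesh(res$vertices, res$faces + 1L)
}

#' Morphological closing of the cortical mask
#'
#' Binary closing (dilation then erosion) of the GM-union-WM indicator
#' with a discrete ball structuring element of radius
#' `ceiling((diameter/2)/lambda)` voxels, implemented by thresholding
#' exact Euclidean distance transforms. The grid is expanded so the
#' dilation never touches the boundary; the closed mask is a superset of
#' the input. Isosurfacing the result gives the smooth "exposed" surface
#' used by closing-based exposed-area measures (15 mm ball by default).
#' A diameter smaller than one voxel is the identity.
#'
#' @param seg a `voxel_segmentation`.
#' @param diameter ball diameter in mm (default 15).
#' @return a `voxel_segmentation`; GM marks closed-mask voxels that are
#'   not WM, so `extract_isosurface(.., "pial")` is the exposed surface.
#' @export
close_mask <- function(seg, diameter = 15) {
  if (diameter <= 0) cs_stop("diameter must be > 0", "cs_validation_error")
  if (diameter < seg$lambda) return(seg)
  rv <- ceiling((diameter / 2) / seg$lambda)
  pad <- as.integer(rv + 1L)
  d0 <- dim(seg$grid)
  dims <- d0 + 2L * pad
  g <- array(VOX_BG, dims)
  g[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <-
    seg$grid
  mask <- g != VOX_BG
  r2 <- as.double(rv)^2 + 1e-9
  dil <- array(squared_edt(as.vector(mask), dims) <= r2, dims)
  clo <- array(squared_edt(as.vector(!dil), dims) > r2, dims)
  out <- array(VOX_BG, dims)
  out[clo] <- VOX_GM
  out[g == VOX_WM] <- VOX_WM
  voxel_segmentation(out, seg$origin - pad * seg$lambda, seg$lambda)
}

#' Convex hull surface
#'
#' Triangulated 3-D convex hull of the mesh vertex set (quickhull),
#' closed and outward-oriented. The hull area of the coarse-grained pial
#' surface is the hemisphere-level exposed area.
#'
#' @param mesh a [triangle_mesh()] with at least 4 non-coplanar vertices.
#' @return a [triangle_mesh()].
#' @export
convex_hull_surface <- function(mesh) {
  v <- mesh$vertices
  f <- tryCatch(quickhull_faces(v),
                error = function(e) cs_stop(conditionMessage(e),
                                            "cs_degenerate_error"))
  used <- sort(unique(as.vector(f)))
  remap <- match(as.vector(f), used)
  triangle_mesh(v[used + 1L, , drop = FALSE],
                matrix(remap, ncol = 3))
}
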