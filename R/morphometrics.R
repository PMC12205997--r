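#' Mesh surface area
#'
#' Sum of triangle areas (mm^2).
#'
#' @param mesh a [triangle_mesh()].
#' @export
mesh_area <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed mesh volume
#'
#' Volume enclosed by a closed mesh via the divergence theorem (sum of
#' signed tetrahedron volumes against the origin); positive for outward
#' orientation, negated if all faces are flipped.
#'
#' @param mesh a closed [triangle_mesh()].
#' @export
mesh_volume <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  if (nrow(f) == 0L || !closed_up_to_orientation(mesh))
    cs_stop("mesh_volume requires a closed mesh", "cs_validation_error")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
         a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
         a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(det) / 6
}

# closed as a surface, allowing globally flipped orientation (each
# undirected edge on exactly 2 faces)
closed_up_to_orientation <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  key <- (pmin(a, b) - 1) * as.double(n) + (pmax(a, b) - 1)
  all(tabulate(match(key, unique(key))) == 2L)
}

#' Hemisphere-level multiscale metrics
#'
#' Combines one scale's products: gray-matter volume from the voxel count
#' (`V_GM = #GM * lambda^3`), total area `A_t` of the coarse-grained pial
#' surface, exposed area `A_e` of the hull (or closing) surface, and the
#' ratio thickness `T = V_GM / A_t`.
#'
#' @param seg the `voxel_segmentation` at this scale.
#' @param pial_cg coarse-grained pial [triangle_mesh()].
#' @param hull exposed-surface [triangle_mesh()] (convex hull by default).
#' @return data.frame with columns `lambda`, `A_t`, `A_e`, `T`, `V_GM`.
#' @export
hemisphere_metrics <- function(seg, pial_cg, hull) {
  a_t <- mesh_area(pial_cg)
  if (a_t <= 0) cs_stop("A_t is zero", "cs_validation_error")
  v_gm <- sum(seg$grid == VOX_GM) * seg$lambda^3
  data.frame(lambda = seg$lambda, A_t = a_t, A_e = mesh_area(hull),
             T = v_gm / a_t, V_GM = v_gm)
}

#' Transfer labels to a re-rendered surface
#'
#' Each vertex of the coarse mesh takes the label of the Euclidean-nearest
#' vertex of the original mesh; exact ties resolve to the lowest original
#' vertex index, so the transfer is deterministic.
#'
#' @param coarse target [triangle_mesh()].
#' @param original source [triangle_mesh()] carrying `labels`.
#' @param labels [vertex_labels()] aligned to `original`.
#' @return [vertex_labels()] aligned to `coarse`.
#' @export
transfer_labels <- function(coarse, original, labels) {
  if (nrow(original$vertices) == 0L)
    cs_stop("original mesh is empty", "cs_validation_error")
  if (length(labels$labels) != nrow(original$vertices))
    cs_stop("labels not aligned to original mesh", "cs_validation_error")
  idx <- nearest_vertex_idx(coarse$vertices, original$vertices) + 1L
  vertex_labels(labels$labels[idx], labels$name_map)
}

#' Region areas by triangle majority
#'
#' Assigns each triangle to the majority label of its three vertices
#' (2-of-3; a 3-way tie goes to the lowest region code) and sums triangle
#' areas per region. The assignment partitions the triangles, so region
#' areas always sum exactly to the total mesh area.
#'
#' @param mesh a [triangle_mesh()].
#' @param labels [vertex_labels()] aligned to `mesh`.
#' @return named numeric vector of areas (mm^2), one per region present.
#' @export
lobe_areas <- function(mesh, labels) {
  if (length(labels$labels) != nrow(mesh$vertices))
    cs_stop("labels not aligned to mesh", "cs_validation_error")
  f <- mesh$faces
  l1 <- labels$labels[f[, 1]]
  l2 <- labels$labels[f[, 2]]
  l3 <- labels$labels[f[, 3]]
  maj <- ifelse(l1 == l2 | l1 == l3, l1,
         ifelse(l2 == l3, l2, pmin(l1, l2, l3)))
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  area <- sqrt((e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
               (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
               (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2) / 2
  out <- tapply(area, maj, sum)
  res <- stats::setNames(as.numeric(out), names(out))
  # report regions by name where known
  nm <- labels$name_map[names(res)]
  names(res) <- ifelse(is.na(nm), names(res), nm)
  res
}

#' Region mean thickness from vertex distances
#'
#' Per pial vertex, the minimum point-to-triangle distance to the white
#' surface (exact closest-point projection with grid-pruned candidate
#' triangles); region thickness is the mean over that region's vertices.
#' Empty regions yield `NA` rather than zero.
#'
#' @param pial pial [triangle_mesh()].
#' @param white white [triangle_mesh()] (non-empty).
#' @param labels [vertex_labels()] aligned to `pial`.
#' @return list with `thickness` (named per-region means), `n_vertices`
#'   (named counts), `vertex_distance` (per-vertex distances).
#' @export
lobe_thickness <- function(pial, white, labels) {
  if (nrow(white$faces) == 0L)
    cs_stop("white mesh is empty", "cs_validation_error")
  if (length(labels$labels) != nrow(pial$vertices))
    cs_stop("labels not aligned to pial mesh", "cs_validation_error")
  d <- point_to_mesh_distance(pial$vertices, white$vertices,
                              white$faces - 1L)
  codes <- as.integer(names(labels$name_map))
  th <- vapply(codes, function(cd) {
    sel <- labels$labels == cd
    if (!any(sel)) NA_real_ else mean(d[sel])
  }, numeric(1))
  nvert <- vapply(codes, function(cd) sum(labels$labels == cd), integer(1))
  list(thickness = stats::setNames(th, labels$name_map),
       n_vertices = stats::setNames(nvert, labels$name_map),
       vertex_distance = d)
}

#' Redistribute insular metrics into the neighbouring lobes
#'
#' The insula's pial area is divided among the frontal, parietal and
#' temporal lobes in proportion to their own areas (the occipital lobe is
#' untouched), conserving total area exactly. Each recipient's thickness
#' becomes the area-weighted mean of its own thickness and the insula
#' thickness weighted by the transferred-area share, which conserves the
#' area-weighted mean thickness of the five-region set. Any extra area
#' columns (e.g. exposed area) are redistributed with the same
#' proportional rule.
#'
#' @param raw data.frame with a `region` column containing `frontal`,
#'   `parietal`, `temporal`, `occipital`, `insula`, an area column `A_t`,
#'   optionally `T` and further area columns (`A_e`).
#' @return data.frame with the four lobes.
#' @export
redistribute_insula <- function(raw) {
  need <- c("frontal", "parietal", "temporal", "occipital", "insula")
  if (!all(need %in% raw$region))
    cs_stop("raw metrics must contain the 5 regions", "cs_validation_error")
  raw <- raw[match(need, raw$region), , drop = FALSE]
  rec <- c("frontal", "parietal", "temporal")
  a <- raw$A_t
  names(a) <- raw$region
  denom <- sum(a[rec])
  if (denom <= 0)
    cs_stop("all recipient lobe areas are zero", "cs_validation_error")
  share <- a[rec] / denom
  transferred <- a["insula"] * share
  out <- raw[raw$region != "insula", , drop = FALSE]
  rownames(out) <- NULL
  sel <- match(rec, out$region)
  out$A_t[sel] <- a[rec] + transferred
  if ("A_e" %in% names(raw) && !all(is.na(raw$A_e))) {
    ae <- raw$A_e; names(ae) <- raw$region
    ae_denom <- sum(ae[rec])
    if (ae_denom > 0)
      out$A_e[sel] <- ae[rec] + ae["insula"] * ae[rec] / ae_denom
  }
  if ("T" %in% names(raw) && !all(is.na(raw$T))) {
    tt <- raw$T; names(tt) <- raw$region
    if (!is.na(tt["insula"]) && a["insula"] > 0) {
      out$T[sel] <- (a[rec] * tt[rec] + transferred * tt["insula"]) /
        (a[rec] + transferred)
    }
  }
  out
}

#' Sweep configuration
#'
#' @param ae_mode hemisphere exposed-area definition: convex `"hull"`
#'   (default) or morphological `"closing"` surface.
#' @param closing_diameter ball diameter (mm) for the closing operation.
#' @param smooth pre-smooth masks before isosurfacing (see
#'   [extract_isosurface()]).
#' @param include_native include the native-scale row computed from the
#'   input meshes directly.
#' @param lobes compute lobe-level metrics (requires labels on the pair).
#' @param origin optional fixed voxel-grid origin.
#' @export
sweep_config <- function(ae_mode = c("hull", "closing"),
                         closing_diameter = 15, smooth = TRUE,
                         include_native = TRUE, lobes = TRUE,
                         origin = NULL) {
  list(ae_mode = match.arg(ae_mode), closing_diameter = closing_diameter,
       smooth = smooth, include_native = include_native, lobes = lobes,
       origin = origin)
}

#' Run the multiscale morphometry sweep
#'
#' For every ladder scale: voxelize the pair, re-render the coarse pial
#' and white surfaces, build the hull and (for lobe-level exposed area)
#' the closing surface, compute hemisphere metrics, transfer lobe labels
#' from the original pial surface, and redistribute the insula. One
#' native-scale entry is computed from the input meshes directly (total
#' area from triangles, hemisphere thickness as the volume/area ratio,
#' exposed area from the hull of the original pial surface).
#'
#' @param pair a `cortical_surface_pair` (labels optional).
#' @param ladder a [scale_ladder()].
#' @param config a [sweep_config()].
#' @param subject_id identifier written into the table.
#' @return tidy data.frame (`subject_id`, `hemisphere`, `structure`,
#'   `lambda` [full-precision character or "native"], `lambda_mm`
#'   [numeric, NA for native], `metric`, `value`).
#' @export
run_scale_sweep <- function(pair, ladder, config = sweep_config(),
                            subject_id = "subject") {
  if (!inherits(ladder, "scale_ladder"))
    cs_stop("ladder must be a scale_ladder", "cs_validation_error")
  do_lobes <- isTRUE(config$lobes) && !is.null(pair$labels)
  if (isTRUE(config$lobes) && is.null(pair$labels)) {
    warning("no labels on pair; computing hemisphere metrics only")
  }
  rows <- list()
  emit <- function(structure_, lambda_chr, lambda_mm, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, hemisphere = pair$hemisphere_id,
      structure = structure_, lambda = lambda_chr, lambda_mm = lambda_mm,
      metric = metric, value = value, stringsAsFactors = FALSE)
  }
  lobe_block <- function(pial_s, white_s, labels_orig, pial_orig,
                         exposed_s, lambda_chr, lambda_mm) {
    labs <- if (identical(pial_s, pial_orig)) labels_orig
            else transfer_labels(pial_s, pial_orig, labels_orig)
    ar <- lobe_areas(pial_s, labs)
    th <- lobe_thickness(pial_s, white_s, labs)
    regions <- c("frontal", "parietal", "temporal", "occipital", "insula")
    raw <- data.frame(region = regions,
                      A_t = as.numeric(ar[regions]),
                      T = as.numeric(th$thickness[regions]))
    raw$A_t[is.na(raw$A_t)] <- 0
    if (!is.null(exposed_s)) {
      labs_e <- transfer_labels(exposed_s, pial_orig, labels_orig)
      ar_e <- lobe_areas(exposed_s, labs_e)
      raw$A_e <- as.numeric(ar_e[regions])
      raw$A_e[is.na(raw$A_e)] <- 0
    }
    lob <- redistribute_insula(raw)
    for (i in seq_len(nrow(lob))) {
      emit(lob$region[i], lambda_chr, lambda_mm, "A_t", lob$A_t[i])
      emit(lob$region[i], lambda_chr, lambda_mm, "T", lob$T[i])
      if ("A_e" %in% names(lob))
        emit(lob$region[i], lambda_chr, lambda_mm, "A_e", lob$A_e[i])
    }
  }

  if (isTRUE(config$include_native)) {
    a_t <- mesh_area(pair$pial)
    v_gm <- mesh_volume(pair$pial) - mesh_volume(pair$white)
    hull <- convex_hull_surface(pair$pial)
    emit("hemisphere", "native", NA_real_, "A_t", a_t)
    emit("hemisphere", "native", NA_real_, "A_e", mesh_area(hull))
    emit("hemisphere", "native", NA_real_, "T", v_gm / a_t)
    emit("hemisphere", "native", NA_real_, "V_GM", v_gm)
    if (do_lobes)
      lobe_block(pair$pial, pair$white, pair$labels, pair$pial,
                 NULL, "native", NA_real_)
  }

  for (lam in ladder$scales) {
    step <- function(e) cs_stop(
      sprintf("scale sweep failed at lambda = %.4g mm: %s", lam,
              conditionMessage(e)), "cs_sweep_error")
    tryCatch({
      seg <- voxelize_pair(pair, lam, origin = config$origin)
      pial_cg <- extract_isosurface(seg, "pial", smooth = config$smooth)
      white_cg <- if (do_lobes && any(seg$grid == VOX_WM))
        extract_isosurface(seg, "white", smooth = config$smooth) else NULL
      hull <- convex_hull_surface(pial_cg)
      closed_surf <- NULL
      if (config$ae_mode == "closing" || do_lobes) {
        cseg <- close_mask(seg, config$closing_diameter)
        closed_surf <- extract_isosurface(cseg, "pial",
                                          smooth = config$smooth)
      }
      ae_mesh <- if (config$ae_mode == "hull") hull else closed_surf
      hm <- hemisphere_metrics(seg, pial_cg, ae_mesh)
      lam_chr <- format_lambda(lam)
      emit("hemisphere", lam_chr, lam, "A_t", hm$A_t)
      emit("hemisphere", lam_chr, lam, "A_e", hm$A_e)
      emit("hemisphere", lam_chr, lam, "T", hm$T)
      emit("hemisphere", lam_chr, lam, "V_GM", hm$V_GM)
      if (do_lobes && !is.null(white_cg))
        lobe_block(pial_cg, white_cg, pair$labels, pair$pial,
                   closed_surf, lam_chr, lam)
    }, error = step)
  }
  do.call(rbind, rows)
}

format_lambda <- function(lam) sprintf("%.17g", lam)

#' Write / read a multiscale metric table
#'
#' CSV with full-precision lambda strings as the join key plus a 2-dp
#' display column, guaranteeing an exact re-read.
#'
#' @param table a table from [run_scale_sweep()].
#' @param path file path.
#' @export
write_multiscale_table <- function(table, path) {
  out <- table
  out$lambda_display <- ifelse(is.na(out$lambda_mm), "native",
                               sprintf("%.2f", out$lambda_mm))
  out$value <- sprintf("%.17g", out$value)
  out$lambda_mm <- ifelse(is.na(table$lambda_mm), "",
                          sprintf("%.17g", table$lambda_mm))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_multiscale_table
#' @export
read_multiscale_table <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  d$value <- as.numeric(d$value)
  d$lambda_mm <- suppressWarnings(as.numeric(d$lambda_mm))
  d$lambda_display <- NULL
  d
}
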