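#' Read a triangle surface
#'
#' Reads a cortical surface mesh from the FreeSurfer binary
#' triangle-surface format or from ASCII PLY. The FreeSurfer dialect is
#' the 3-byte magic `0xFF 0xFF 0xFE`, a creation-comment terminated by two
#' newline bytes, big-endian int32 vertex/face counts, float32 vertex
#' coordinates and int32 0-based face indices. Coordinates are passed
#' through unchanged (mm, in the file's native frame).
#'
#' @param path file path.
#' @param format `"freesurfer"`, `"ply"`, or `"auto"` (by extension:
#'   `.ply` is PLY, anything else FreeSurfer).
#' @return a [triangle_mesh()] with 1-based faces.
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path))
    cs_stop(sprintf("file not found: %s", path), "cs_io_error")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "freesurfer"
  if (format == "freesurfer") read_surface_fs(path) else read_surface_ply(path)
}

read_surface_fs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (length(magic) < 3 ||
      magic[1] != 0xFF || magic[2] != 0xFF || magic[3] != 0xFE)
    cs_stop("not a FreeSurfer binary triangle surface (bad magic bytes)",
            "cs_format_error")
  # creation comment: bytes up to and including two consecutive newlines
  prev <- -1L
  repeat {
    b <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
    if (length(b) == 0)
      cs_stop("truncated surface file (unterminated comment)",
              "cs_parse_error")
    if (b == 10L && prev == 10L) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2, size = 4, endian = "big")
  if (length(counts) < 2 || any(counts < 0))
    cs_stop("truncated surface file (missing counts)", "cs_parse_error")
  nv <- counts[1]; nf <- counts[2]
  v <- readBin(con, "numeric", n = 3 * nv, size = 4, endian = "big")
  if (length(v) < 3 * nv)
    cs_stop("truncated surface file (vertex block)", "cs_parse_error")
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  if (length(f) < 3 * nf)
    cs_stop("truncated surface file (face block)", "cs_parse_error")
  faces <- matrix(f, ncol = 3, byrow = TRUE) + 1L
  if (nf > 0 && (min(faces) < 1 || max(faces) > nv))
    cs_stop("face index out of range", "cs_validation_error")
  triangle_mesh(matrix(v, ncol = 3, byrow = TRUE), faces)
}

read_surface_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    cs_stop("not a PLY file (missing 'ply' magic line)", "cs_format_error")
  if (!grepl("^format\\s+ascii\\s+1\\.0", trimws(lines[2])))
    cs_stop("only ASCII PLY 1.0 is supported", "cs_format_error")
  nv <- nf <- NA_integer_
  i <- 2L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^element\\s+vertex\\s+", ln))
      nv <- as.integer(sub("^element\\s+vertex\\s+", "", ln))
    if (grepl("^element\\s+face\\s+", ln))
      nf <- as.integer(sub("^element\\s+face\\s+", "", ln))
    if (ln == "end_header") break
    i <- i + 1L
  }
  if (i > length(lines) || is.na(nv) || is.na(nf))
    cs_stop("malformed PLY header", "cs_parse_error")
  body <- lines[(i + 1L):length(lines)]
  if (length(body) < nv + nf)
    cs_stop("truncated PLY body", "cs_parse_error")
  vtx <- t(vapply(body[seq_len(nv)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])
  }, numeric(3), USE.NAMES = FALSE))
  fc <- t(vapply(body[nv + seq_len(nf)], function(s) {
    xs <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (xs[1] != 3L)
      cs_stop("non-triangular PLY face", "cs_parse_error")
    xs[2:4]
  }, integer(3), USE.NAMES = FALSE))
  if (nf > 0 && (min(fc) < 0 || max(fc) >= nv))
    cs_stop("face index out of range", "cs_validation_error")
  triangle_mesh(vtx, fc + 1L)
}

#' Write a triangle surface
#'
#' Writes a mesh in the FreeSurfer binary triangle-surface format or
#' ASCII PLY 1.0, readable back by [read_surface()]. Refuses to write an
#' empty surface.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"freesurfer"`, `"ply"`, or `"auto"` (by extension).
#' @export
write_surface <- function(mesh, path, format = c("auto", "freesurfer", "ply")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (nrow(mesh$vertices) == 0L)
    cs_stop("refusing to write a surface with 0 vertices",
            "cs_validation_error")
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "freesurfer"
  if (format == "freesurfer") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
    writeBin(charToRaw("created by cortexscales\n\n"), con)
    writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)),
             con, size = 4, endian = "big")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
    writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4, endian = "big")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "ply", "format ascii 1.0",
      "comment created by cortexscales",
      sprintf("element vertex %d", nrow(mesh$vertices)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(mesh$faces)),
      "property list uchar int vertex_indices",
      "end_header"), con)
    writeLines(apply(mesh$vertices, 1, function(r)
      paste(format(r, digits = 9, trim = TRUE, scientific = FALSE),
            collapse = " ")), con)
    if (nrow(mesh$faces) > 0)
      writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                       mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Per-vertex region labels
#'
#' @param labels integer vector of region codes, one per mesh vertex.
#' @param name_map named character vector mapping code (as name) to
#'   region name.
#' @return object of class `vertex_labels`.
#' @export
vertex_labels <- function(labels, name_map) {
  labels <- as.integer(labels)
  if (is.null(names(name_map)))
    cs_stop("name_map must be named by region code", "cs_validation_error")
  miss <- setdiff(unique(labels), as.integer(names(name_map)))
  if (length(miss))
    cs_stop(sprintf("label code(s) %s missing from name_map",
                    paste(miss, collapse = ", ")), "cs_validation_error")
  structure(list(labels = labels, name_map = name_map),
            class = "vertex_labels")
}

#' @export
print.vertex_labels <- function(x, ...) {
  cat(sprintf("vertex_labels: %d vertices, %d regions (%s)\n",
              length(x$labels), length(x$name_map),
              paste(x$name_map, collapse = ", ")))
  invisible(x)
}

#' Read per-vertex labels
#'
#' Reads vertex region labels from a FreeSurfer `.annot` file (big-endian;
#' `(vertex, packed-RGB label)` pairs followed by the old-format
#' colortable) or from a CSV with header `vertex,label` (and optionally
#' `name`). The label count must match the mesh vertex count.
#'
#' @param path file path.
#' @param mesh the mesh the labels belong to (for the count check).
#' @param format `"annot"`, `"csv"`, or `"auto"` (by extension).
#' @return a [vertex_labels()] aligned to mesh vertex order.
#' @export
read_vertex_labels <- function(path, mesh,
                               format = c("auto", "annot", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.annot$", path, ignore.case = TRUE)) "annot" else "csv"
  nv <- nrow(mesh$vertices)
  if (format == "csv") {
    d <- read.csv(path, check.names = FALSE)
    if (!all(c("vertex", "label") %in% names(d)))
      cs_stop("label CSV must have columns 'vertex,label'",
              "cs_format_error")
    if (nrow(d) != nv)
      cs_stop(sprintf("label count (%d) does not match vertex count (%d)",
                      nrow(d), nv), "cs_validation_error")
    off <- if (min(d$vertex) == 0L) 1L else 0L
    ord <- order(d$vertex)
    d <- d[ord, ]
    if (!identical(as.integer(d$vertex + off), seq_len(nv)))
      cs_stop("label CSV must list every vertex exactly once",
              "cs_validation_error")
    labs <- as.integer(d$label)
    if ("name" %in% names(d)) {
      nm <- tapply(as.character(d$name), d$label, `[`, 1)
      name_map <- stats::setNames(as.character(nm), names(nm))
    } else {
      codes <- sort(unique(labs))
      name_map <- stats::setNames(paste0("region_", codes), codes)
    }
    vertex_labels(labs, name_map)
  } else {
    read_annot(path, nv)
  }
}

read_annot <- function(path, nv) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(n) == 0 || n < 0)
    cs_stop("truncated .annot file", "cs_parse_error")
  if (n != nv)
    cs_stop(sprintf("label count (%d) does not match vertex count (%d)",
                    n, nv), "cs_validation_error")
  pairs <- readBin(con, "integer", n = 2 * n, size = 4, endian = "big")
  if (length(pairs) < 2 * n)
    cs_stop("truncated .annot file (vertex/label pairs)", "cs_parse_error")
  vtx <- pairs[seq(1, 2 * n, by = 2)]
  lab <- pairs[seq(2, 2 * n, by = 2)]
  labs <- integer(n)
  labs[vtx + 1L] <- lab
  tag <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  name_map <- NULL
  if (length(tag) == 1 && tag == 1L) {  # old-format colortable present
    ne <- readBin(con, "integer", n = 1, size = 4, endian = "big")
    fl <- readBin(con, "integer", n = 1, size = 4, endian = "big")
    readBin(con, "raw", n = fl)  # source filename, unused
    nms <- character(ne); codes <- integer(ne)
    for (i in seq_len(ne)) {
      ln <- readBin(con, "integer", n = 1, size = 4, endian = "big")
      nmraw <- readBin(con, "raw", n = ln)
      rgba <- readBin(con, "integer", n = 4, size = 4, endian = "big")
      nms[i] <- rawToChar(nmraw[nmraw != as.raw(0)])
      codes[i] <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
    }
    name_map <- stats::setNames(nms, codes)
  }
  if (is.null(name_map)) {
    codes <- sort(unique(labs))
    name_map <- stats::setNames(paste0("region_", codes), codes)
  }
  vertex_labels(labs, name_map)
}

#' Write per-vertex labels
#'
#' Writers matching [read_vertex_labels()]: CSV (`vertex,label,name`,
#' 0-based vertex indices) or FreeSurfer `.annot` with an old-format
#' colortable whose packed-RGB entries are the label codes.
#'
#' @param labels a [vertex_labels()].
#' @param path output path.
#' @param format `"annot"`, `"csv"`, or `"auto"` (by extension).
#' @export
write_vertex_labels <- function(labels, path,
                                format = c("auto", "annot", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.annot$", path, ignore.case = TRUE)) "annot" else "csv"
  n <- length(labels$labels)
  if (format == "csv") {
    d <- data.frame(vertex = seq_len(n) - 1L, label = labels$labels,
                    name = labels$name_map[as.character(labels$labels)])
    write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(n, con, size = 4, endian = "big")
    pairs <- rbind(seq_len(n) - 1L, labels$labels)
    writeBin(as.integer(pairs), con, size = 4, endian = "big")
    writeBin(1L, con, size = 4, endian = "big")  # old colortable tag
    codes <- as.integer(names(labels$name_map))
    writeBin(length(codes), con, size = 4, endian = "big")
    src <- charToRaw("cortexscales")
    writeBin(length(src), con, size = 4, endian = "big")
    writeBin(src, con)
    for (i in seq_along(codes)) {
      nm <- charToRaw(labels$name_map[i])
      writeBin(length(nm), con, size = 4, endian = "big")
      writeBin(nm, con)
      code <- codes[i]
      r <- code %% 256L
      g <- (code %/% 256L) %% 256L
      b <- (code %/% 65536L) %% 256L
      writeBin(as.integer(c(r, g, b, 0L)), con, size = 4, endian = "big")
    }
  }
  invisible(path)
}
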