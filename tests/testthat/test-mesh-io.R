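test_that("FreeSurfer surface round-trip preserves geometry", {
  # 2-triangle fixture (open mesh is fine for raw I/O)
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1)),
                     rbind(c(1, 2, 3), c(2, 4, 3)))
  tf <- tempfile(fileext = ".white")
  write_surface(m, tf, format = "freesurfer")
  m2 <- read_surface(tf, format = "freesurfer")
  expect_identical(m2$faces, m$faces)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-7)

  ic <- icosphere(4)  # 2562 vertices, float32 precision round-trip
  tf2 <- tempfile(fileext = ".pial")
  write_surface(ic, tf2)
  ic2 <- read_surface(tf2)
  expect_identical(ic2$faces, ic$faces)
  expect_lt(max(abs(ic2$vertices - ic$vertices)), 2^-23)
})

test_that("FreeSurfer reader rejects bad files instead of guessing", {
  tf <- tempfile()
  writeBin(as.raw(c(0xFF, 0xFF, 0xFD, 0x00)), tf)
  expect_error(read_surface(tf, format = "freesurfer"),
               class = "cs_format_error")
  # truncated after a valid magic + comment
  con <- file(tf, "wb")
  writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
  writeBin(charToRaw("x\n\n"), con)
  writeBin(c(5L, 4L), con, size = 4, endian = "big")
  close(con)
  expect_error(read_surface(tf, format = "freesurfer"),
               class = "cs_parse_error")
  expect_error(read_surface(tempfile(), format = "freesurfer"),
               class = "cs_io_error")
})

test_that("PLY writer emits a valid header and round-trips", {
  cube <- cube_mesh()
  tf <- tempfile(fileext = ".ply")
  write_surface(cube, tf)
  lines <- readLines(tf)
  expect_true("element vertex 8" %in% lines)
  expect_true("element face 12" %in% lines)
  m2 <- read_surface(tf)
  expect_identical(m2$faces, cube$faces)
  expect_equal(m2$vertices, cube$vertices, tolerance = 1e-8)

  notply <- tempfile(fileext = ".ply")
  writeLines(c("plx", "format ascii 1.0"), notply)
  expect_error(read_surface(notply), class = "cs_format_error")
})

test_that("writers refuse empty meshes and invalid faces are caught", {
  empty <- triangle_mesh(matrix(numeric(0), 0, 3),
                         matrix(integer(0), 0, 3))
  expect_error(write_surface(empty, tempfile()),
               class = "cs_validation_error")
  expect_error(triangle_mesh(rbind(c(0, 0, 0)), rbind(c(1, 1, 2))),
               class = "cs_validation_error")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                             rbind(c(1, 2, 3))),
               class = "cs_validation_error")
})

test_that("round-trip identity holds for random closed meshes, both formats", {
  set.seed(7)
  for (i in 1:5) {
    m <- random_closed_mesh(30)
    for (fmt in c("freesurfer", "ply")) {
      tf <- tempfile(fileext = if (fmt == "ply") ".ply" else "")
      write_surface(m, tf, format = fmt)
      m2 <- read_surface(tf, format = fmt)
      expect_identical(m2$faces, m$faces)
      expect_lt(max(abs(m2$vertices - m$vertices)) /
                  max(1, max(abs(m$vertices))), 1e-6)
    }
  }
})

test_that("CSV vertex labels read back aligned and checked", {
  mesh <- triangle_mesh(matrix(rnorm(15), 5, 3),
                        rbind(c(1, 2, 3), c(3, 4, 5)))
  tf <- tempfile(fileext = ".csv")
  writeLines(c("vertex,label", paste(0:4, 0:4, sep = ",")), tf)
  lab <- read_vertex_labels(tf, mesh)
  expect_identical(lab$labels, 0:4)

  writeLines(c("vertex,label", paste(0:3, 0:3, sep = ",")), tf)
  expect_error(read_vertex_labels(tf, mesh),
               class = "cs_validation_error")
})

test_that("annot files written by the package round-trip", {
  pair <- labelled_sphere_pair()
  tf <- tempfile(fileext = ".annot")
  write_vertex_labels(pair$labels, tf)
  lab2 <- read_vertex_labels(tf, pair$pial)
  expect_identical(lab2$labels, pair$labels$labels)
  expect_identical(sort(unname(lab2$name_map)),
                   sort(unname(pair$labels$name_map)))
})

test_that("labels require a complete name_map", {
  expect_error(vertex_labels(c(1L, 2L), c(`1` = "a")),
               class = "cs_validation_error")
})
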