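# On-disk format round trips and hand-assembled byte fixtures. All formats
# are big-endian 32-bit; fixtures are built byte-by-byte from the format
# layout, independently of the writers.

be_int <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
be_float <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "big")

test_that("triangle surface files round trip exactly", {
  tet <- tetrahedron()
  path <- withr::local_tempfile()
  write_surface(tet, path)
  bytes <- readBin(path, "raw", 3)
  expect_identical(bytes, as.raw(c(0xff, 0xff, 0xfe)))
  back <- read_surface(path)
  expect_equal(back$coords, tet$coords, tolerance = 1e-7)
  expect_identical(back$faces, tet$faces)

  # randomized instances: float32 coords survive a second round trip bit
  # for bit
  set.seed(42)
  for (i in 1:5) {
    ico <- icosphere(radius = runif(1, 5, 50), subdivisions = 1)
    ico$coords <- ico$coords + rnorm(length(ico$coords), sd = 0.01)
    write_surface(ico, path)
    once <- read_surface(path)
    write_surface(once, path)
    twice <- read_surface(path)
    expect_identical(twice$coords, once$coords)
    expect_identical(twice$faces, ico$faces)
  }
})

test_that("a hand-assembled triangle-format file parses field by field", {
  path <- withr::local_tempfile()
  bytes <- c(as.raw(c(0xff, 0xff, 0xfe)),
             charToRaw("fixture\n\n"),
             be_int(3), be_int(1),
             be_float(c(0, 0, 0, 1, 0, 0, 0, 1, 0)),
             be_int(c(0, 1, 2)))
  writeBin(bytes, path)
  s <- read_surface(path)
  expect_equal(nrow(s$coords), 3)
  expect_equal(nrow(s$faces), 1)
  expect_equal(s$coords[2, ], c(1, 0, 0))
  expect_identical(s$faces[1, ], c(1L, 2L, 3L))
})

test_that("wrong magic numbers and invariant violations are rejected", {
  path <- withr::local_tempfile()
  writeBin(c(as.raw(c(0xff, 0xff, 0xff)), be_int(c(2, 0, 1)),
             be_float(c(1, 2))), path)
  expect_error(read_surface(path), "0xFF 0xFF 0xFF")
  bad <- tetrahedron()
  bad$faces[1, 1] <- 9L
  expect_error(write_surface(bad, path), "face indices")
})

test_that("scalar field files round trip and validate their counts", {
  path <- withr::local_tempfile()
  vals <- c(-0.3, 0, 0.2)
  write_scalar_field(fs_field(vals, "mean_curvature"), path)
  back <- read_scalar_field(path, expected_n = 3)
  expect_equal(back$values, vals, tolerance = 1e-7)
  expect_error(read_scalar_field(path, expected_n = 10), "3 vertices")

  # hand-assembled 2-vertex file
  writeBin(c(as.raw(c(0xff, 0xff, 0xff)), be_int(c(2, 0, 1)),
             be_float(c(1.5, -1.5))), path)
  expect_equal(read_scalar_field(path)$values, c(1.5, -1.5))

  # multiple values per vertex unsupported
  writeBin(c(as.raw(c(0xff, 0xff, 0xff)), be_int(c(2, 0, 3)),
             be_float(rep(0, 6))), path)
  expect_error(read_scalar_field(path), "3 values per vertex")

  expect_no_error(write_scalar_field(fs_field(c(1, 2), "thickness"), path))
  expect_error(fs_field(c(1, -2), "thickness"), "non-negative")
})

test_that("annotations round trip with a version-2 colour table", {
  tab <- data.frame(id = 1:4,
                    name = c("G_temp_sup-G_T_transv", "S_temporal_transverse",
                             "G_temp_sup-Plan_tempo", "Lat_Fis-post"),
                    R = c(10L, 20L, 30L, 40L), G = c(1L, 2L, 3L, 4L),
                    B = c(5L, 6L, 7L, 8L))
  roi <- c(1L, 1L, 3L, -1L, 2L, 4L, -1L, 3L)
  parc <- fs_parcellation(roi, tab)
  path <- withr::local_tempfile()
  write_annotation(parc, path)
  back <- read_annotation(path)
  expect_identical(back$vertex_roi, roi)
  expect_identical(back$roi_table$name, tab$name)
  expect_identical(back$roi_table$R, tab$R)
})

test_that("unknown packed colours read back as unassigned", {
  # 3-vertex fixture built from raw bytes: two vertices carry the gyrus
  # colour, one an alien colour not present in the table
  c_hg <- 10 + 256 * 20 + 65536 * 30
  c_alien <- 99 + 256 * 99
  ct_name <- "G_temp_sup-G_T_transv"
  bytes <- c(be_int(3),
             be_int(c(0, c_hg, 1, c_hg, 2, c_alien)),
             be_int(1), be_int(-2), be_int(1),
             be_int(6), charToRaw("x.ctb"), as.raw(0),
             be_int(1),
             be_int(0), be_int(nchar(ct_name) + 1), charToRaw(ct_name),
             as.raw(0), be_int(c(10, 20, 30, 0)))
  path <- withr::local_tempfile()
  writeBin(bytes, path)
  parc <- read_annotation(path)
  expect_identical(sum(parc$vertex_roi == 1L), 2L)
  expect_identical(parc$vertex_roi[3], -1L)
})

test_that("annotations without a v2 colour table are rejected", {
  bytes <- c(be_int(1), be_int(c(0, 123)))
  path <- withr::local_tempfile()
  writeBin(bytes, path)
  expect_error(read_annotation(path), "colour table")
  writeBin(c(bytes, be_int(1), be_int(5)), path)  # old inline table
  expect_error(read_annotation(path), "version-2")
})

test_that("ASCII labels round trip, including the empty label", {
  lab <- fs_label(c(3, 6, 10), coords = rbind(c(1, 2, 3), c(4, 5, 6),
                                              c(7, 8, 9)),
                  stat = c(0.5, 0, -1), name = "probe")
  path <- withr::local_tempfile(fileext = ".label")
  write_label(lab, path)
  lines <- readLines(path)
  expect_match(lines[1], "^#!ascii")
  expect_equal(as.integer(lines[2]), 3)
  back <- read_label(path)
  expect_identical(back$vertices, c(3L, 6L, 10L))
  expect_equal(back$coords, lab$coords)
  expect_equal(back$stat, lab$stat)

  empty <- fs_label(integer(0))
  write_label(empty, path)
  expect_identical(read_label(path)$vertices, integer(0))
})

test_that("label readers refuse count/row mismatches", {
  path <- withr::local_tempfile()
  writeLines(c("#!ascii label broken", "3", "0 0 0 0 0", "1 0 0 0 0"), path)
  expect_error(read_label(path), "announces 3")
})
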