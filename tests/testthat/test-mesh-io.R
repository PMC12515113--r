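test_that("unit cube STL round-trips in binary and ASCII", {
  cube <- box_mesh()
  expect_equal(nrow(cube$triangles), 12)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  fb <- tempfile(fileext = ".stl")
  write_mesh(cube, fb)
  back <- read_mesh(fb)
  expect_equal(nrow(back$triangles), 12)
  expect_lt(max(abs(range(back$vertices) - c(0, 1))), 1e-5)
  fa <- tempfile(fileext = ".stl")
  write_mesh(cube, fa, ascii = TRUE)
  back_a <- read_mesh(fa)
  expect_equal(nrow(back_a$triangles), 12)
  expect_equal(mesh_volume(back_a), mesh_volume(back), tolerance = 1e-6)
})

test_that("phantom mandible mesh round-trips volume to 1e-6 relative", {
  ph <- phantom_full()
  mesh <- extract_mesh(ph$gt_original)
  f <- tempfile(fileext = ".stl")
  write_mesh(mesh, f)
  back <- read_mesh(f)
  expect_equal(nrow(back$triangles), nrow(mesh$triangles))
  v0 <- mesh_volume(mesh)
  expect_lt(abs(mesh_volume(back) - v0) / abs(v0), 1e-6)
  expect_lt(max(abs(apply(back$vertices, 2, range) -
                     apply(mesh$vertices, 2, range))), 1e-5)
})

test_that("degenerate meshes and malformed files are rejected", {
  expect_error(surface_mesh(matrix(0, 3, 3), matrix(integer(0), 0, 3)),
               "at least one triangle")
  expect_error(surface_mesh(matrix(0, 2, 3), matrix(c(1L, 2L, 3L), 1)),
               "out of range")
  bad <- tempfile(fileext = ".stl")
  writeBin(as.raw(rep(0, 90)), bad)  # header claims facets the file lacks
  expect_error(read_mesh(bad), "malformed|short")
})
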