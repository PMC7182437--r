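test_that("triangle_mesh validates its inputs", {
  expect_s3_class(tetrahedron_mesh(), "triangle_mesh")
  expect_error(triangle_mesh(matrix(1, 3, 2), matrix(1L, 1, 3)), "n x 3")
  expect_error(triangle_mesh(rbind(c(0, 0, NA)), matrix(1L, 1, 3)), "finite")
  expect_error(triangle_mesh(diag(3), rbind(c(1L, 2L, 4L))), "out of range")
})

test_that("edges, edge lengths and volume are consistent on a tetrahedron", {
  m <- tetrahedron_mesh()
  e <- mesh_edges(m)
  expect_equal(nrow(e), 6)
  expect_equal(sort(edge_lengths(m)), sort(c(1, 1, 1, sqrt(2), sqrt(2), sqrt(2))))
  expect_equal(mesh_volume(m), 1 / 6, tolerance = 1e-12)
})

test_that("sphere mesh volume approaches the analytic value", {
  s <- sphere_mesh(2, 32, 48)
  expect_equal(mesh_volume(s), 4 / 3 * pi * 8, tolerance = 0.01)
})

test_that("medio-lateral mirroring negates x, preserves volume, and is an involution", {
  m <- sphere_mesh(1.5, 10, 14, center = c(2, -1, 3))
  mm <- mirror_ml(m)
  expect_equal(mm$vertices[, 1], -m$vertices[, 1])
  expect_equal(mm$vertices[, 2:3], m$vertices[, 2:3])
  # winding flip keeps outward orientation: signed volume invariant
  expect_equal(mesh_volume(mm), mesh_volume(m), tolerance = 1e-12)
  expect_equal(mirror_ml(mm), m)
  expect_equal(mirror_ml(triangle_mesh(rbind(c(1, 2, 3), c(0, 1, 0), c(0, 0, 1)),
                                       rbind(1:3)))$vertices[1, ],
               c(-1, 2, 3))
})

test_that("PLY, OBJ and STL round-trip a mesh", {
  m <- tetrahedron_mesh()
  for (ext in c(".ply", ".obj")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mesh(m, f)
    m2 <- read_mesh(f)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(m2$faces, m$faces)
  }
  # ascii PLY
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, f, binary = FALSE)
  expect_equal(read_mesh(f)$vertices, m$vertices, tolerance = 1e-7)
  # STL is a facet soup; welding restores the 4 shared vertices
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, f)
  m3 <- read_mesh(f)
  expect_equal(nrow(m3$vertices), 4)
  expect_equal(sort(as.numeric(m3$vertices)), sort(as.numeric(m$vertices)),
               tolerance = 1e-6)
})

test_that("unreadable or unsupported files raise format errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  file.create(f)
  expect_error(read_mesh(f), "empty")
  expect_error(read_mesh(tempfile(fileext = ".ply")), "exist")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines("1 2 3", f2)
  expect_error(read_mesh(f2), "unsupported")
  f3 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not", "a ply"), f3)
  expect_error(read_mesh(f3), "PLY")
})
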