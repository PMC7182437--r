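test_that("Taubin smoothing is identity at 0 iterations and volume-preserving", {
  s <- sphere_mesh(10, 28, 42)
  expect_identical(smooth_mesh(s, 0), s)
  sm <- smooth_mesh(s, 10)
  expect_equal(nrow(sm$vertices), nrow(s$vertices))
  expect_lt(abs(mesh_volume(sm) - mesh_volume(s)) / mesh_volume(s), 0.01)
})

test_that("smoothing strictly reduces radial noise on a noisy sphere", {
  set.seed(11)
  s <- sphere_mesh(10, 20, 30)
  noisy <- triangle_mesh(s$vertices + matrix(rnorm(length(s$vertices), 0, 0.15),
                                             ncol = 3), s$faces)
  dev <- function(m) mean(abs(sqrt(rowSums(m$vertices^2)) - 10))
  expect_lt(dev(smooth_mesh(noisy, 5)), dev(noisy))
})

test_that("quadric decimation hits the target count with small surface deviation", {
  s <- sphere_mesh(10, 50, 100)  # ~4902 vertices
  expect_gt(nrow(s$vertices), 4800)
  d <- decimate(s, 1000)
  expect_lt(abs(nrow(d$vertices) - 1000), 21)
  expect_lt(surface_distances(s, d)[["hausdorff"]], 0.02 * 10)
  # watertight in, watertight out: every edge still on exactly two faces
  e <- rbind(d$faces[, 1:2], d$faces[, 2:3], d$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("decimation contracts are enforced", {
  s <- sphere_mesh(5, 8, 10)
  expect_identical(decimate(s, nrow(s$vertices)), s)
  expect_error(decimate(s, 3), "at least 4")
  expect_error(decimate(s, nrow(s$vertices) + 1), "exceeds")
  # non-manifold input (edge shared by 3 faces) is an explicit error
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                             c(0, -1, 0)),
                       rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(decimate(bad, 4), "non-manifold")
})

test_that("isotropic remeshing reaches the target edge length", {
  s <- sphere_mesh(10, 24, 36)
  r <- remesh_to_edge_length(s, 1.0)
  expect_lt(abs(mean(edge_lengths(r)) - 1.0), 0.1)
  # surface stays a sphere
  expect_lt(max(abs(sqrt(rowSums(r$vertices^2)) - 10)), 0.15)
  # halving the edge length roughly quadruples the vertex count
  r2 <- remesh_to_edge_length(s, 0.5)
  ratio <- nrow(r2$vertices) / nrow(r$vertices)
  expect_gt(ratio, 4 * 0.7)
  expect_lt(ratio, 4 * 1.3)
  expect_error(remesh_to_edge_length(s, 1000), "bounding box")
  expect_error(remesh_to_edge_length(s, -1), "positive")
})

test_that("surface distances match the brute-force double-loop oracle", {
  set.seed(21)
  mk <- function() {
    v <- matrix(runif(24, -1, 1), ncol = 3)
    triangle_mesh(v, t(utils::combn(8, 3))[sample(56, 10), ])
  }
  a <- mk(); b <- mk()
  expect_equal(surface_distances(a, b), oracle_surface_distances(a, b),
               tolerance = 1e-9)
  # symmetry and identity
  expect_equal(surface_distances(a, b), surface_distances(b, a))
  expect_equal(unname(surface_distances(a, a)), c(0, 0))
})

test_that("a rigidly offset plane patch measures exactly its offset", {
  g <- expand.grid(x = 0:4, y = 0:4)
  v <- cbind(g$x, g$y, 0)
  f <- do.call(rbind, lapply(0:3, function(i) do.call(rbind, lapply(0:3, function(j) {
    a <- i * 5 + j + 1; b <- a + 1; cc <- a + 5; d <- cc + 1
    rbind(c(a, b, cc), c(b, d, cc))
  }))))
  p1 <- triangle_mesh(v, f)
  p2 <- triangle_mesh(cbind(v[, 1:2], 1), f)
  expect_equal(surface_distances(p1, p2)[["hausdorff"]], 1.0)
  expect_equal(surface_distances(p1, p2)[["mean"]], 1.0)
})
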