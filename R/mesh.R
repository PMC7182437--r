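#' Triangle surface mesh
#'
#' Constructs the package's basic geometry container: a triangle surface mesh
#' with vertex coordinates in millimetres. The package-wide coordinate
#' convention is x = medio-lateral (+lateral for a right-side bone),
#' y = antero-posterior (+anterior), z = proximo-distal (+proximal);
#' the frontal plane is (x, z), the sagittal plane (y, z) and the axial
#' plane (x, y).
#'
#' @param vertices numeric matrix, n x 3, finite coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   counter-clockwise winding for outward normals.
#' @return an object of class `triangle_mesh` with elements `vertices`
#'   and `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    rng <- range(faces)
    if (rng[1] < 1L || rng[2] > nrow(vertices))
      stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @exportS3Method base::print
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Mesh edges
#'
#' Unique undirected edges of a mesh.
#'
#' @param mesh a `triangle_mesh`.
#' @return two-column integer matrix of vertex index pairs, `i < j`.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Edge length statistics
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of unique edge lengths in mm.
#' @export
edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume via the divergence theorem (sum of signed tetrahedra to the
#' origin). Positive for outward-oriented closed surfaces.
#'
#' @param mesh a `triangle_mesh`.
#' @return signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ab <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ac <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# vertex adjacency as a sparse row-stochastic averaging operator
vertex_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Medio-lateral mirroring
#'
#' Negates the medio-lateral (x) coordinate and flips face winding so that
#' outward normals are preserved. Applying it twice returns the original
#' mesh. Used to map left-side bones onto the right-side convention.
#'
#' @param mesh a `triangle_mesh`.
#' @return the mirrored `triangle_mesh`.
#' @export
mirror_ml <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  triangle_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])
}

#' UV sphere mesh
#'
#' Latitude/longitude triangulated sphere, used as a smooth closed test
#' surface and as a building block for synthetic bones.
#'
#' @param radius sphere radius (mm).
#' @param n_theta number of latitude bands (>= 3).
#' @param n_phi number of longitude steps (>= 3).
#' @param center sphere centre, length-3.
#' @return a `triangle_mesh`.
#' @export
sphere_mesh <- function(radius = 1, n_theta = 16, n_phi = 24,
                        center = c(0, 0, 0)) {
  stopifnot(n_theta >= 3, n_phi >= 3, radius > 0)
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  ring <- function(t) cbind(radius * sin(t) * cos(phi),
                            radius * sin(t) * sin(phi),
                            radius * cos(t))
  v <- do.call(rbind, lapply(theta, ring))
  north <- c(0, 0, radius)
  south <- c(0, 0, -radius)
  v <- rbind(north, v, south)
  i_n <- 1L
  i_s <- nrow(v)
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(i_n, idx(1L, j), idx(1L, j + 1L))
  }
  nb <- length(theta)
  for (i in seq_len(nb - 1L)) {
    for (j in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, cc, b)
      faces[[length(faces) + 1L]] <- c(b, cc, d)
    }
  }
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(i_s, idx(nb, j + 1L), idx(nb, j))
  }
  m <- triangle_mesh(v, do.call(rbind, faces))
  m$vertices <- sweep(m$vertices, 2, center, "+")
  m
}

# Rigid rotation helpers --------------------------------------------------

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a),
           0, 1, 0,
           -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

apply_rigid <- function(points, R, t = c(0, 0, 0)) {
  sweep(points %*% t(R), 2, t, "+")
}
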