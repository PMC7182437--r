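#' Taubin mesh smoothing
#'
#' Low-pass smoothing with alternating positive/negative Laplacian steps
#' (lambda/mu scheme), which attenuates surface noise while largely
#' preserving the enclosed volume, unlike plain Laplacian smoothing which
#' shrinks the surface. Zero iterations returns the input unchanged; the
#' vertex count is never altered.
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of lambda/mu step pairs (>= 0).
#' @param lambda positive smoothing step (default 0.5).
#' @param mu negative un-shrinking step (default -0.53, slightly larger in
#'   magnitude than `lambda` as in Taubin's scheme).
#' @return the smoothed `triangle_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations, lambda = 0.5, mu = -0.53) {
  stopifnot(is_triangle_mesh(mesh), iterations >= 0)
  if (iterations == 0) return(mesh)
  A <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    lap <- as.matrix(A %*% v) / deg - v
    v <- v + lambda * lap
    lap <- as.matrix(A %*% v) / deg - v
    v <- v + mu * lap
  }
  triangle_mesh(v, mesh$faces)
}

#' Mesh decimation by quadric edge collapse
#'
#' Reduces the vertex count to approximately `target_vertices` by
#' iteratively collapsing the edge with minimal quadric error, with
#' link-condition and normal-flip guards so that a manifold watertight
#' input stays manifold and watertight.
#'
#' @param mesh a `triangle_mesh`; must be manifold (every edge on at most
#'   two faces); non-manifold input is an error, not silently repaired.
#' @param target_vertices requested vertex count, between 4 and the current
#'   count.
#' @return the decimated `triangle_mesh`.
#' @export
decimate <- function(mesh, target_vertices) {
  stopifnot(is_triangle_mesh(mesh))
  n <- nrow(mesh$vertices)
  if (target_vertices < 4) stop("target_vertices must be at least 4")
  if (target_vertices > n)
    stop("target_vertices exceeds current vertex count")
  if (target_vertices == n) return(mesh)
  out <- cpp_decimate(mesh$vertices, mesh$faces, as.integer(target_vertices))
  triangle_mesh(out$vertices, out$faces)
}

#' Isotropic remeshing to a target edge length
#'
#' Incremental remeshing (edge split/collapse/flip plus tangential
#' relaxation with back-projection onto the input surface) producing a
#' triangulation whose mean edge length approximates `target_edge_mm`.
#' Used to resample the reference bone pair before building dense
#' correspondences.
#'
#' @param mesh a `triangle_mesh`.
#' @param target_edge_mm target mean edge length in mm (> 0 and smaller
#'   than the mesh bounding-box diagonal).
#' @param iterations remeshing sweeps (default 10).
#' @return the remeshed `triangle_mesh`.
#' @export
remesh_to_edge_length <- function(mesh, target_edge_mm, iterations = 10) {
  stopifnot(is_triangle_mesh(mesh))
  if (target_edge_mm <= 0) stop("target_edge_mm must be positive")
  bbox <- apply(mesh$vertices, 2, range)
  diag_len <- sqrt(sum((bbox[2, ] - bbox[1, ])^2))
  if (target_edge_mm >= diag_len)
    stop("target_edge_mm is larger than the mesh bounding box")
  out <- cpp_remesh(mesh$vertices, mesh$faces, target_edge_mm,
                    as.integer(iterations))
  triangle_mesh(out$vertices, out$faces)
}

#' Closest points on a mesh surface
#'
#' For each query point, the nearest point on the triangle set of `mesh`
#' (point-to-triangle, not point-to-vertex).
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a `triangle_mesh`.
#' @return list with `points` (n x 3 closest surface points), `dist`
#'   (n distances, mm) and `face` (1-based triangle index).
#' @export
closest_on_surface <- function(points, mesh) {
  stopifnot(is_triangle_mesh(mesh))
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_closest_on_mesh(points, mesh$vertices, mesh$faces)
}

#' Symmetric surface distances between two meshes
#'
#' Vertex-sampled symmetric Hausdorff distance (maximum over both directed
#' maxima of vertex-to-opposing-surface distances) and symmetric mean
#' distance. Distances are point-to-triangle, so meshes with different
#' vertex placement but coincident surfaces measure (near) zero.
#'
#' @param a,b `triangle_mesh` objects.
#' @return named numeric vector `c(hausdorff = , mean = )` in mm.
#' @export
surface_distances <- function(a, b) {
  stopifnot(is_triangle_mesh(a), is_triangle_mesh(b))
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    stop("meshes must be non-empty")
  dab <- cpp_closest_on_mesh(a$vertices, b$vertices, b$faces)$dist
  dba <- cpp_closest_on_mesh(b$vertices, a$vertices, a$faces)$dist
  c(hausdorff = max(max(dab), max(dba)),
    mean = mean(c(dab, dba)))
}
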