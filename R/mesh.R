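#' Triangle meshes
#'
#' A `cr_mesh` is an indexed triangle surface: an `n x 3` vertex matrix in mm
#' and an `m x 3` face matrix of 1-based vertex indices. An optional
#' per-vertex scalar channel carries deviation values for colour-mapped
#' export.
#'
#' @param vertices Numeric matrix, one vertex per row (mm).
#' @param faces Integer matrix, one face per row, 1-based vertex indices.
#' @param scalar Optional numeric per-vertex channel (length `nrow(vertices)`).
#' @return An object of class `cr_mesh`.
#' @export
mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("vertex positions must be finite", call. = FALSE)
  if (!is.null(scalar)) stopifnot(length(scalar) == nrow(vertices))
  structure(list(vertices = vertices, faces = faces, scalar = scalar),
            class = "cr_mesh")
}

#' @export
print.cr_mesh <- function(x, ...) {
  cat(sprintf("<cr_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), sum(face_areas(x))))
  invisible(x)
}

#' Per-face quantities
#'
#' `face_areas()`, `face_centroids()` and `face_normals()` return per-face
#' areas (mm^2), centroids and unit normals. `mesh_area()` is the total
#' surface area.
#'
#' @param m A [mesh()].
#' @export
face_areas <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, c_ - a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_centroids <- function(m) {
  (m$vertices[m$faces[, 1], , drop = FALSE] +
     m$vertices[m$faces[, 2], , drop = FALSE] +
     m$vertices[m$faces[, 3], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @export
face_normals <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, c_ - a)
  nrm <- sqrt(rowSums(cr^2))
  cr / pmax(nrm, 1e-300)
}

#' @rdname face_areas
#' @export
mesh_area <- function(m) sum(face_areas(m))

vec_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Signed enclosed volume of a closed mesh
#'
#' Positive when face normals point outward (divergence theorem).
#' @param m A [mesh()].
#' @export
mesh_signed_volume <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(rowSums(a * vec_cross(b, c_))) / 6
}

# edge table: one row per undirected edge occurrence, columns (vmin, vmax)
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Boundary structure and Euler characteristic
#'
#' `boundary_faces()` flags faces owning at least one boundary edge (an edge
#' used by exactly one face of the given face subset). `euler_characteristic()`
#' returns V - E + F of the used sub-complex.
#'
#' @param m A [mesh()].
#' @param face_ids Optional subset of face indices to treat as the active
#'   surface (defaults to all faces).
#' @return `boundary_faces()`: logical vector over `face_ids`.
#' @export
boundary_faces <- function(m, face_ids = NULL) {
  if (is.null(face_ids)) face_ids <- seq_len(nrow(m$faces))
  faces <- m$faces[face_ids, , drop = FALSE]
  e <- mesh_edges(faces)
  key <- e[, 1] * (nrow(m$vertices) + 1) + e[, 2]
  shared <- key %in% key[duplicated(key)]
  rowSums(matrix(!shared, nrow = length(face_ids))) > 0
}

#' @rdname boundary_faces
#' @export
euler_characteristic <- function(m, face_ids = NULL) {
  if (is.null(face_ids)) face_ids <- seq_len(nrow(m$faces))
  faces <- m$faces[face_ids, , drop = FALSE]
  v <- length(unique(as.vector(faces)))
  e <- nrow(unique(mesh_edges(faces)))
  v - e + nrow(faces)
}

#' @rdname boundary_faces
#' @export
count_boundary_edges <- function(m, face_ids = NULL) {
  if (is.null(face_ids)) face_ids <- seq_len(nrow(m$faces))
  e <- mesh_edges(m$faces[face_ids, , drop = FALSE])
  key <- e[, 1] * (nrow(m$vertices) + 1) + e[, 2]
  sum(!(key %in% key[duplicated(key)]))
}

#' Rigidly transform a mesh
#'
#' @param m A [mesh()].
#' @param transform A [rigid_transform()].
#' @export
transform_mesh <- function(m, transform) {
  mesh(transform_points(transform, m$vertices), m$faces, m$scalar)
}

#' Area-weighted random points on a mesh surface
#'
#' Samples faces with probability proportional to area, then uniform
#' barycentric coordinates. Draws from the current RNG stream.
#'
#' @param m A [mesh()].
#' @param n Number of points.
#' @param face_ids Optional face subset to sample from.
#' @return List with `points` (n x 3) and `face` (face index per point).
#' @export
sample_surface_points <- function(m, n, face_ids = NULL) {
  if (is.null(face_ids)) face_ids <- seq_len(nrow(m$faces))
  ar <- face_areas(m)[face_ids]
  pick <- face_ids[sample.int(length(face_ids), n, replace = TRUE, prob = ar)]
  r1 <- sqrt(runif(n))
  r2 <- runif(n)
  u <- 1 - r1
  v <- r1 * (1 - r2)
  w <- r1 * r2
  a <- m$vertices[m$faces[pick, 1], , drop = FALSE]
  b <- m$vertices[m$faces[pick, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[pick, 3], , drop = FALSE]
  list(points = u * a + v * b + w * c_, face = pick)
}

# drop zero-area and degenerate faces, keep vertex set
drop_degenerate_faces <- function(m, tol = 1e-12) {
  keep <- face_areas(m) > tol &
    m$faces[, 1] != m$faces[, 2] &
    m$faces[, 2] != m$faces[, 3] &
    m$faces[, 1] != m$faces[, 3]
  mesh(m$vertices, m$faces[keep, , drop = FALSE], m$scalar)
}

# drop vertices not referenced by any face, reindexing faces
compact_mesh <- function(m) {
  used <- sort(unique(as.vector(m$faces)))
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  mesh(m$vertices[used, , drop = FALSE],
       matrix(remap[m$faces], ncol = 3),
       if (!is.null(m$scalar)) m$scalar[used] else NULL)
}
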