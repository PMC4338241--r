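#' Extract a threshold isosurface from a volume
#'
#' Marching-cubes family extraction (six-tetrahedron cell decomposition with
#' linear interpolation along edges) of the surface where intensity crosses
#' `threshold_hu`. The mesh is in mm (spacing and origin applied) with
#' normals oriented outward from the above-threshold region. Bone thresholds
#' of 300-500 HU are typical for CT-like intensities. No smoothing is
#' applied.
#'
#' @param vol A [volume()].
#' @param threshold_hu Iso level, strictly between the volume's min and max
#'   intensity.
#' @return A [mesh()].
#' @export
extract_isosurface <- function(vol, threshold_hu) {
  stopifnot(inherits(vol, "cr_volume"))
  rng <- range(vol$intensities)
  if (threshold_hu <= rng[1] || threshold_hu >= rng[2]) {
    stop(sprintf("no surface: threshold %g outside intensity range [%g, %g]",
                 threshold_hu, rng[1], rng[2]), call. = FALSE)
  }
  res <- .cpp_isosurface(as.numeric(vol$intensities), dim(vol$intensities),
                         vol$spacing_mm, vol$origin_mm, threshold_hu)
  if (nrow(res$faces) == 0) {
    stop("no surface: threshold produced an empty isosurface", call. = FALSE)
  }
  drop_degenerate_faces(mesh(res$vertices, res$faces))
}

#' Remove small disconnected components
#'
#' Drops connected components (faces joined through shared vertices) whose
#' face count is below `min_fraction` of the largest component's. The
#' largest component is always preserved exactly; ties at the threshold are
#' retained. This is the cleanup step that removes small floating artifact
#' shells.
#'
#' @param m A [mesh()].
#' @param min_fraction Fraction in (0, 1); default 0.01.
#' @return A [mesh()] with vertices reindexed.
#' @export
clean_components <- function(m, min_fraction = 0.01) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  if (nrow(m$faces) == 0) return(m)
  comp <- face_components(m)
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_fraction * max(sizes))
  compact_mesh(mesh(m$vertices, m$faces[comp %in% keep_comp, , drop = FALSE],
                    m$scalar))
}

# connected component id per face (faces connected through shared vertices)
face_components <- function(m) {
  nf <- nrow(m$faces)
  nv <- nrow(m$vertices)
  edges <- rbind(cbind(m$faces[, 1], nv + seq_len(nf)),
                 cbind(m$faces[, 2], nv + seq_len(nf)),
                 cbind(m$faces[, 3], nv + seq_len(nf)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- igraph::components(g)$membership
  fid <- memb[nv + seq_len(nf)]
  as.integer(factor(fid))
}

#' Decimate a mesh to a face budget
#'
#' If the face count is within the budget the mesh is returned unchanged.
#' Otherwise vertices are clustered on a uniform grid (cell size chosen by
#' bisection to meet the budget), each cluster is replaced by its mean
#' position, and degenerate or duplicated faces are dropped. The geometric
#' drift is bounded by the cluster cell diagonal and reported in the
#' `"decimation_drift_mm"` attribute (maximum vertex displacement, mm).
#'
#' @param m A [mesh()].
#' @param max_faces Face budget (>= 4); the default mirrors the common
#'   100,000-polygon cap of surface registration workflows.
#' @return A [mesh()] with at most `max_faces` faces.
#' @export
decimate_to_budget <- function(m, max_faces = 100000) {
  stopifnot(max_faces >= 4)
  if (nrow(m$faces) <= max_faces) return(m)
  # initial cell size from the area heuristic (2 faces per clustered vertex),
  # then multiplicative adjustment until within budget
  g <- sqrt(2 * mesh_area(m) / max_faces)
  best <- NULL
  for (it in 1:25) {
    cand <- cluster_decimate(m, g)
    nf <- nrow(cand$faces)
    if (nf <= max_faces) {
      best <- cand
      if (nf > 0.8 * max_faces || it > 5) break
      g <- g / 1.15
    } else {
      g <- g * max(1.1, sqrt(nf / max_faces))
    }
  }
  if (is.null(best)) best <- cand
  best
}

cluster_decimate <- function(m, cell) {
  key <- floor(sweep(m$vertices, 2, apply(m$vertices, 2, min)) / cell)
  id <- key[, 1] + 4096 * (key[, 2] + 4096 * key[, 3])
  ci <- match(id, unique(id))
  newv <- cbind(rowsum(m$vertices[, 1], ci), rowsum(m$vertices[, 2], ci),
                rowsum(m$vertices[, 3], ci)) / as.vector(rowsum(rep(1, length(ci)), ci))
  drift <- max(sqrt(rowSums((m$vertices - newv[ci, , drop = FALSE])^2)))
  nf <- matrix(ci[m$faces], ncol = 3)
  ok <- nf[, 1] != nf[, 2] & nf[, 2] != nf[, 3] & nf[, 1] != nf[, 3]
  nf <- nf[ok, , drop = FALSE]
  # drop duplicate faces (same vertex triple regardless of order)
  s1 <- as.numeric(pmin(nf[, 1], nf[, 2], nf[, 3]))
  s3 <- as.numeric(pmax(nf[, 1], nf[, 2], nf[, 3]))
  s2 <- as.numeric(nf[, 1]) + as.numeric(nf[, 2]) + as.numeric(nf[, 3]) - s1 - s3
  skey <- s1 + (s3 + 1) * (s2 + (s3 + 1) * s3)
  nf <- nf[!duplicated(skey), , drop = FALSE]
  out <- drop_degenerate_faces(compact_mesh(mesh(newv, nf)))
  attr(out, "decimation_drift_mm") <- drift
  out
}

#' Region masks
#'
#' A region mask is a labelled subset of face indices of a mesh, naming a
#' reference structure or a measurement patch.
#'
#' @param face_ids Integer face indices (non-empty).
#' @param label Region label (e.g. `"AC"`, `"F"`, `"ZygL"`, `"ZygR"`).
#' @export
region_mask <- function(face_ids, label = "region") {
  face_ids <- as.integer(face_ids)
  if (length(face_ids) == 0) stop("region mask must be non-empty", call. = FALSE)
  structure(list(face_ids = face_ids, label = label), class = "cr_region_mask")
}

#' @export
print.cr_region_mask <- function(x, ...) {
  cat(sprintf("<cr_region_mask> '%s': %d faces\n", x$label, length(x$face_ids)))
  invisible(x)
}

#' Select mesh faces inside a region descriptor
#'
#' Membership is decided by the face centroid (deterministic and
#' area-additive): a face belongs to the region when its centroid lies
#' inside the descriptor solid.
#'
#' @param m A [mesh()].
#' @param descriptor A region descriptor (an atlas entry).
#' @param label Optional label override.
#' @return A [region_mask()].
#' @export
select_region <- function(m, descriptor, label = descriptor$name) {
  cen <- face_centroids(m)
  inside <- solid_contains(descriptor, cen)
  if (!any(inside)) {
    stop(sprintf("region miss: descriptor '%s' selects no faces", label),
         call. = FALSE)
  }
  region_mask(which(inside), label)
}

#' Grow a circular surface patch of a target area
#'
#' Starting from the face closest to `center`, faces are absorbed in order
#' of geodesic distance (shortest path over the face-adjacency graph,
#' weighted by centroid-to-centroid distance) until the cumulative face area
#' reaches `area_mm2`. Used for the 5 mm^2 fiducial test areas.
#'
#' @param m A [mesh()].
#' @param center 3D point (mm); must lie within `max_dist` of the surface.
#' @param area_mm2 Target patch area (mm^2).
#' @param label Patch label.
#' @param max_dist Maximum allowed distance from `center` to the surface
#'   (mm), default 2.
#' @param tree Optional [mesh_tree()] of `m`.
#' @return A [region_mask()] with attribute `"achieved_area_mm2"`.
#' @export
circular_patch <- function(m, center, area_mm2, label = "patch", max_dist = 2,
                           tree = NULL) {
  cp <- closest_point(m, matrix(center, ncol = 3), tree = tree)
  if (cp$distance[1] > max_dist) {
    stop(sprintf("patch center is %.2f mm from the surface (limit %g mm)",
                 cp$distance[1], max_dist), call. = FALSE)
  }
  seed_face <- cp$face[1]
  areas <- face_areas(m)
  cen <- face_centroids(m)
  seed_c <- cen[seed_face, ]

  # restrict the graph to a Euclidean neighbourhood of the seed (grown if the
  # contained area turns out insufficient), then run Dijkstra on the subset
  r_cand <- max(3 * sqrt(area_mm2 / pi), 3)
  repeat {
    cand <- which(sqrt(colSums((t(cen) - seed_c)^2)) <= r_cand)
    if (sum(areas[cand]) >= 1.5 * area_mm2 || length(cand) == nrow(m$faces)) break
    r_cand <- r_cand * 1.6
  }
  sub_faces <- m$faces[cand, , drop = FALSE]
  adj <- face_adjacency_edges(mesh(m$vertices, sub_faces))
  seed_loc <- match(seed_face, cand)
  n <- length(cand)
  dist <- rep(Inf, n)
  dist[seed_loc] <- 0
  visited <- logical(n)
  in_patch <- logical(n)
  acc <- 0
  frontier <- seed_loc
  dq <- 0
  while (length(frontier) > 0 && acc < area_mm2) {
    i <- which.min(dq)
    f <- frontier[i]
    d0 <- dq[i]
    frontier <- frontier[-i]
    dq <- dq[-i]
    if (visited[f]) next
    visited[f] <- TRUE
    in_patch[f] <- TRUE
    acc <- acc + areas[cand[f]]
    for (g in adj[[f]]) {
      if (!visited[g]) {
        nd <- d0 + sqrt(sum((cen[cand[f], ] - cen[cand[g], ])^2))
        if (nd < dist[g]) {
          dist[g] <- nd
          frontier <- c(frontier, g)
          dq <- c(dq, nd)
        }
      }
    }
  }
  if (acc < area_mm2) {
    stop("patch growth exhausted the reachable surface before reaching the target area",
         call. = FALSE)
  }
  mask <- region_mask(cand[in_patch], label)
  attr(mask, "achieved_area_mm2") <- acc
  attr(mask, "geodesic_radius_mm") <- max(dist[in_patch])
  mask
}

# adjacency list over faces sharing an edge
face_adjacency_edges <- function(m) {
  nf <- nrow(m$faces)
  e <- mesh_edges(m$faces)
  fid <- rep(seq_len(nf), 3)
  key <- paste(e[, 1], e[, 2])
  sp <- split(fid, key)
  adj <- vector("list", nf)
  for (grp in sp) {
    if (length(grp) >= 2) {
      for (f in grp) adj[[f]] <- c(adj[[f]], setdiff(grp, f))
    }
  }
  lapply(adj, unique)
}
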