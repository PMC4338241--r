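#' Surface deviation over a patch
#'
#' For sample points on the patch of the (already superimposed) result mesh,
#' closest-point vectors to the reference mesh are computed. `D` is the mean
#' Euclidean norm of those vectors (mm); `Dx`, `Dy`, `Dz` are the mean
#' signed per-axis components of result minus reference (so the sign of a
#' component records the direction of bias; positive along an axis means
#' the result surface lies on the positive side of the reference). Sampling
#' is deterministic: each patch face contributes its centroid, its three
#' edge midpoints and its three vertices, area-weighted per face.
#'
#' @param result_mesh Mesh being assessed (superimposed T1), a [mesh()].
#' @param reference_mesh Reference mesh (T0).
#' @param patch A [region_mask()] on `result_mesh`.
#' @param max_correspondence_mm Correspondence cutoff: if the nearest
#'   reference surface is farther than this for the whole patch, the patch
#'   cannot be compared (default 10 mm, the grey-zone rule).
#' @param reference_tree Optional [mesh_tree()] of `reference_mesh`.
#' @return A one-row [tibble::tibble()] (`patch_or_point`, `D`, `Dx`, `Dy`,
#'   `Dz`, `n_samples`).
#' @export
patch_deviation <- function(result_mesh, reference_mesh, patch,
                            max_correspondence_mm = 10,
                            reference_tree = NULL) {
  stopifnot(inherits(patch, "cr_region_mask"))
  sp <- patch_sample_points(result_mesh, patch$face_ids)
  res <- if (is.null(reference_tree)) {
    .cpp_closest_point(reference_mesh$vertices, reference_mesh$faces, sp$points)
  } else {
    .cpp_bvh_query(reference_tree, sp$points)
  }
  if (min(res$distance) > max_correspondence_mm) {
    stop(sprintf("correspondence failure: no reference surface within %g mm of patch '%s'",
                 max_correspondence_mm, patch$label), call. = FALSE)
  }
  vec <- sp$points - res$point
  w <- sp$weights / sum(sp$weights)
  tibble::tibble(
    patch_or_point = patch$label,
    D = sum(w * sqrt(rowSums(vec^2))),
    Dx = sum(w * vec[, 1]),
    Dy = sum(w * vec[, 2]),
    Dz = sum(w * vec[, 3]),
    n_samples = nrow(sp$points)
  )
}

# deterministic area-weighted samples: per face, centroid + edge midpoints +
# vertices with Simpson-like weights
patch_sample_points <- function(m, face_ids) {
  a <- m$vertices[m$faces[face_ids, 1], , drop = FALSE]
  b <- m$vertices[m$faces[face_ids, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[face_ids, 3], , drop = FALSE]
  ar <- face_areas(m)[face_ids]
  pts <- rbind((a + b + c_) / 3,
               (a + b) / 2, (b + c_) / 2, (a + c_) / 2,
               a, b, c_)
  wt <- c(ar * 0.45, rep(ar / 3 * 0.45, 3), rep(ar / 3 * 0.10, 3))
  list(points = pts, weights = wt)
}

#' Superimposition accuracy statistic
#'
#' The accuracy measure of a superimposition: the patch deviation `D` is
#' computed at the three fiducial test areas (anterior sella surface and
#' the posterior right/left foramen rim), and their sum is divided by
#' three, i.e. `D_accuracy` is the mean of the three patch deviations.
#' These areas are form-stable, so a perfect superimposition gives 0.
#'
#' @param result_mesh,reference_mesh Superimposed and reference [mesh()]es.
#' @param fiducial_patches List of 3 [region_mask()]s on `result_mesh`.
#' @param reference_tree Optional [mesh_tree()] of `reference_mesh`.
#' @return A list with `patch_deviations` (3-row tibble) and `D_accuracy`.
#' @export
accuracy_D <- function(result_mesh, reference_mesh, fiducial_patches,
                       reference_tree = NULL) {
  stopifnot(length(fiducial_patches) == 3)
  recs <- lapply(fiducial_patches, function(p) {
    tryCatch(patch_deviation(result_mesh, reference_mesh, p,
                             reference_tree = reference_tree),
             error = function(e) stop(sprintf("patch '%s': %s", p$label,
                                              conditionMessage(e)), call. = FALSE))
  })
  tab <- dplyr::bind_rows(recs)
  list(patch_deviations = tab, D_accuracy = mean(tab$D))
}

#' Landmark displacement under a superimposition
#'
#' The measured structural change at a landmark: the T1 landmark is mapped
#' into the T0 frame by the superimposition transform and compared with the
#' T0 landmark. `D` is the Euclidean norm, `Dx/Dy/Dz` the signed
#' components of `transform(landmark_t1) - landmark_t0`.
#'
#' @param landmark_t0,landmark_t1 3-vectors in their native frames (mm).
#' @param superimposition [rigid_transform()] mapping T1 frame to T0 frame.
#' @param label Point label.
#' @return One-row tibble (`patch_or_point`, `D`, `Dx`, `Dy`, `Dz`,
#'   `n_samples = 1`).
#' @export
landmark_displacement <- function(landmark_t0, landmark_t1, superimposition,
                                  label = "point") {
  v <- transform_points(superimposition, landmark_t1) - landmark_t0
  tibble::tibble(patch_or_point = label, D = sqrt(sum(v^2)),
                 Dx = v[1], Dy = v[2], Dz = v[3], n_samples = 1L)
}

#' Signed per-vertex deviation field
#'
#' For every vertex of `result_mesh`, the signed distance to
#' `reference_mesh` (positive when the vertex lies on the outward-normal
#' side of the reference surface), clamped to `[-cap_mm, cap_mm]`. Vertices
#' with no correspondence within `max_correspondence_mm` are set `NA`
#' (exported grey). The field is attached as the mesh scalar channel, ready
#' for colour-mapped export.
#'
#' @inheritParams patch_deviation
#' @param cap_mm Clamp bound (> 0).
#' @return `result_mesh` with the signed deviation as its scalar channel.
#' @export
deviation_field <- function(result_mesh, reference_mesh, cap_mm = 2,
                            max_correspondence_mm = 10) {
  stopifnot(cap_mm > 0)
  res <- .cpp_closest_point(reference_mesh$vertices, reference_mesh$faces,
                            result_mesh$vertices)
  nrm <- face_normals(reference_mesh)[res$face, , drop = FALSE]
  vec <- result_mesh$vertices - res$point
  signed <- sign_or_one(rowSums(vec * nrm)) * res$distance
  signed <- pmin(pmax(signed, -cap_mm), cap_mm)
  signed[res$distance > max_correspondence_mm] <- NA_real_
  mesh(result_mesh$vertices, result_mesh$faces, scalar = signed)
}

sign_or_one <- function(x) ifelse(x >= 0, 1, -1)

#' Trim a mesh to an axis-aligned box
#'
#' Keeps faces whose vertices all lie inside the box. An empty result is
#' returned as an empty mesh flagged with attribute `"empty"`.
#'
#' @param m A [mesh()].
#' @param box 2 x 3 matrix `rbind(lower, upper)` (mm).
#' @export
trim_to_roi <- function(m, box) {
  box <- as.matrix(box)
  stopifnot(all(dim(box) == c(2, 3)))
  inside_v <- m$vertices[, 1] >= box[1, 1] & m$vertices[, 1] <= box[2, 1] &
    m$vertices[, 2] >= box[1, 2] & m$vertices[, 2] <= box[2, 2] &
    m$vertices[, 3] >= box[1, 3] & m$vertices[, 3] <= box[2, 3]
  keep <- inside_v[m$faces[, 1]] & inside_v[m$faces[, 2]] & inside_v[m$faces[, 3]]
  if (!any(keep)) {
    out <- mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- compact_mesh(mesh(m$vertices, m$faces[keep, , drop = FALSE], m$scalar))
  attr(out, "empty") <- FALSE
  out
}
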