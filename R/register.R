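#' ICP parameters
#'
#' @param tolerance_mm Registration precision ceiling (mm): iteration also
#'   stops once the trimmed RMS pair distance falls below this value.
#'   Default 0.3, read as an upper bound; the change-based stopping rule
#'   below is normally what terminates iteration, well under this ceiling.
#' @param max_iterations Iteration cap (default 100).
#' @param sample_count Number of area-weighted sample points drawn on the
#'   moving surface (default 20000, subject to the mesh polygon budget).
#' @param boundary_reject Reject pairs whose closest point lies on a face at
#'   the boundary of the target surface/mask (default `TRUE`).
#' @param trim_fraction Fraction of worst pairs (by distance) discarded each
#'   iteration (default 0.1).
#' @param min_pairs Minimum surviving pairs for a valid solve (default 50).
#' @param convergence_eps_mm Stop when the trimmed RMS changes by less than
#'   this between iterations (default 1e-8 mm).
#' @param seed Seed for the surface sampling.
#' @export
icp_params <- function(tolerance_mm = 0.3, max_iterations = 100,
                       sample_count = 20000, boundary_reject = TRUE,
                       trim_fraction = 0.1, min_pairs = 50,
                       convergence_eps_mm = 1e-8, seed = 1L) {
  stopifnot(tolerance_mm > 0, trim_fraction >= 0, trim_fraction < 1,
            max_iterations >= 1, sample_count >= 10, min_pairs >= 3,
            convergence_eps_mm > 0)
  structure(list(tolerance_mm = tolerance_mm, max_iterations = max_iterations,
                 sample_count = sample_count, boundary_reject = boundary_reject,
                 trim_fraction = trim_fraction, min_pairs = min_pairs,
                 convergence_eps_mm = convergence_eps_mm, seed = as.integer(seed)),
            class = "icp_params")
}

#' Rigid landmark registration (three points)
#'
#' Least-squares rigid transform (no scaling, no reflection) mapping the
#' source landmark triple onto the target triple, by SVD of the
#' cross-covariance (Kabsch). Exact when the two triples are congruent.
#'
#' @param source_pts,target_pts 3 x 3 matrices, one labelled point per row.
#' @return A [rigid_transform()] with attribute `"rms_mm"` (post-fit RMS).
#' @export
kabsch_3p <- function(source_pts, target_pts) {
  kabsch(source_pts, target_pts, require_n = 3)
}

#' Build a spatial index for repeated closest-point queries
#'
#' Returns an opaque AABB-tree handle for the mesh (optionally restricted
#' to a mask). Queries through the handle are identical to
#' [closest_point()] without one; the handle only saves the per-call build.
#'
#' @param m A [mesh()].
#' @param mask Optional [region_mask()].
#' @export
mesh_tree <- function(m, mask = NULL) {
  face_ids <- if (is.null(mask)) seq_len(nrow(m$faces)) else mask$face_ids
  .cpp_bvh_build(m$vertices, m$faces[face_ids, , drop = FALSE])
}

kabsch <- function(source_pts, target_pts, require_n = NULL) {
  src <- as.matrix(source_pts)
  tgt <- as.matrix(target_pts)
  stopifnot(nrow(src) == nrow(tgt), ncol(src) == 3)
  if (!is.null(require_n)) stopifnot(nrow(src) == require_n)
  if (nrow(src) == 3) {
    ar <- 0.5 * sqrt(sum(vec_cross(src[2, , drop = FALSE] - src[1, , drop = FALSE],
                                   src[3, , drop = FALSE] - src[1, , drop = FALSE])^2))
    if (ar <= 1e-6) {
      stop("degenerate landmarks: points are collinear or coincident", call. = FALSE)
    }
  }
  mu_s <- colMeans(src)
  mu_t <- colMeans(tgt)
  H <- crossprod(sweep(src, 2, mu_s), sweep(tgt, 2, mu_t))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, mu_t - as.numeric(R %*% mu_s))
  res <- transform_points(tr, src) - tgt
  attr(tr, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Coarse pre-alignment from anatomical landmarks
#'
#' Emulates the manual first registration on the Frankfurt-horizontal plane
#' and the infraorbital line: aligns the plane through the two infraorbital
#' points and the left mastoid point, the infraorbital line direction, and
#' the landmark centroids. Implemented as a rigid least-squares fit on that
#' landmark triple, which is exact for noiseless congruent landmarks.
#'
#' @param landmarks_src,landmarks_ref Landmark matrices with named rows
#'   containing at least `InfraorbitalL`, `InfraorbitalR` and `MastoidL`.
#' @return A [rigid_transform()] mapping source into reference frame.
#' @export
coarse_align <- function(landmarks_src, landmarks_ref) {
  need <- c("InfraorbitalL", "InfraorbitalR", "MastoidL")
  missing_src <- setdiff(need, rownames(landmarks_src))
  missing_ref <- setdiff(need, rownames(landmarks_ref))
  if (length(missing_src) || length(missing_ref)) {
    stop("coarse_align requires landmarks: ",
         paste(unique(c(missing_src, missing_ref)), collapse = ", "), call. = FALSE)
  }
  kabsch_3p(landmarks_src[need, , drop = FALSE], landmarks_ref[need, , drop = FALSE])
}

#' Closest point on a mesh
#'
#' Exact point-to-triangle minimum over the mesh (accelerated by an AABB
#' tree; results identical to an exhaustive scan, with the lowest face id
#' winning exact ties). When a `mask` is given, only masked faces are
#' candidates and `is_boundary` refers to the mask's boundary.
#'
#' @param m A [mesh()].
#' @param query Point matrix (n x 3) or single point.
#' @param mask Optional [region_mask()] restricting candidate faces.
#' @param boundary Compute the `is_boundary` flag (slower on large meshes;
#'   default `TRUE` when a mask is given, else `FALSE`).
#' @return List with `point` (n x 3 surface points), `face` (face ids into
#'   `m`), `distance` (mm) and `is_boundary` (flag per query: the hit face
#'   owns a boundary edge of the active surface; `NA` when not computed).
#' @param tree Optional prebuilt spatial index from [mesh_tree()] for the
#'   same mesh (and same mask, if any); avoids rebuilding the index in
#'   loops.
#' @export
closest_point <- function(m, query, mask = NULL, boundary = !is.null(mask),
                          tree = NULL) {
  vec <- is.null(dim(query))
  q <- if (vec) matrix(query, ncol = 3) else as.matrix(query)
  face_ids <- if (is.null(mask)) seq_len(nrow(m$faces)) else mask$face_ids
  res <- if (is.null(tree)) {
    .cpp_closest_point(m$vertices, m$faces[face_ids, , drop = FALSE], q)
  } else {
    .cpp_bvh_query(tree, q)
  }
  bnd_flag <- if (boundary) {
    boundary_faces(m, face_ids)[res$face]
  } else {
    rep(NA, nrow(q))
  }
  list(point = res$point,
       face = face_ids[res$face],
       distance = res$distance,
       is_boundary = bnd_flag)
}

# reference-path oracle used in tests: plain R exhaustive scan
closest_point_bruteforce_R <- function(m, query) {
  q <- as.matrix(query)
  nf <- nrow(m$faces)
  best_d <- rep(Inf, nrow(q))
  best_f <- rep(NA_integer_, nrow(q))
  best_p <- q * NA
  for (f in seq_len(nf)) {
    a <- m$vertices[m$faces[f, 1], ]
    b <- m$vertices[m$faces[f, 2], ]
    c_ <- m$vertices[m$faces[f, 3], ]
    for (i in seq_len(nrow(q))) {
      cp <- closest_on_triangle_R(q[i, ], a, b, c_)
      d <- sqrt(sum((q[i, ] - cp)^2))
      if (d < best_d[i]) {
        best_d[i] <- d
        best_f[i] <- f
        best_p[i, ] <- cp
      }
    }
  }
  list(point = best_p, face = best_f, distance = best_d)
}

# closest point on one triangle via constrained barycentric projection
closest_on_triangle_R <- function(p, a, b, c_) {
  # candidate set: projection onto the plane clamped to the triangle,
  # the three edges, and the three vertices
  edge_pt <- function(u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    u + min(max(t, 0), 1) * (v - u)
  }
  n <- pracma_cross(b - a, c_ - a)
  cands <- list(edge_pt(a, b), edge_pt(b, c_), edge_pt(c_, a))
  if (sum(n^2) > 0) {
    n <- n / sqrt(sum(n^2))
    proj <- p - sum((p - a) * n) * n
    # barycentric test
    v0 <- b - a; v1 <- c_ - a; v2 <- proj - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) cands <- c(cands, list(proj))
  }
  d <- vapply(cands, function(x) sum((p - x)^2), numeric(1))
  cands[[which.min(d)]]
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Robust point-to-plane ICP registration
#'
#' Registers a moving mesh (optionally restricted to a region mask) onto a
#' fixed mesh (optionally masked). Each iteration: (1) the fixed sample
#' points drawn area-weighted on the moving mask are moved by the current
#' transform; (2) closest points on the fixed surface are found; (3) pairs
#' hitting the boundary of the fixed surface are rejected (robust rule of
#' the RICP engine) and the worst `trim_fraction` by distance are trimmed;
#' (4) the point-to-plane error (distance to the tangent plane of the fixed
#' surface) is minimised by a small-angle linearised solve composed via the
#' exponential map; (5) iteration stops when the trimmed RMS changes by less
#' than `convergence_eps_mm`, falls below `tolerance_mm` x 1e-5, or the
#' iteration cap is hit. A halving line search keeps the trimmed RMS
#' non-increasing.
#'
#' @param moving,fixed [mesh()] objects.
#' @param moving_mask,fixed_mask Optional [region_mask()]s.
#' @param init Initial [rigid_transform()] (e.g. from [coarse_align()]).
#' @param params An [icp_params()].
#' @return List with `transform` (total transform, composed with `init`)
#'   and `report` (iterations, RMS history, pairs used, convergence flag).
#' @export
icp_point_to_plane <- function(moving, fixed, moving_mask = NULL,
                               fixed_mask = NULL, init = identity_transform(),
                               params = icp_params()) {
  mv_faces <- if (is.null(moving_mask)) seq_len(nrow(moving$faces)) else moving_mask$face_ids
  fx_faces <- if (is.null(fixed_mask)) seq_len(nrow(fixed$faces)) else fixed_mask$face_ids
  if (!length(mv_faces) || !length(fx_faces)) {
    stop("empty registration mask", call. = FALSE)
  }

  set.seed(params$seed)
  smp <- sample_surface_points(moving, params$sample_count, mv_faces)
  pts0 <- smp$points

  fx_sub <- fixed$faces[fx_faces, , drop = FALSE]
  fx_normals <- face_normals(fixed)[fx_faces, , drop = FALSE]
  fx_boundary <- boundary_faces(fixed, fx_faces)
  fx_tree <- .cpp_bvh_build(fixed$vertices, fx_sub)

  total <- init
  rms_history <- numeric(0)
  pairs_used <- NA_integer_
  converged <- FALSE
  prev_rms <- Inf

  correspond <- function(tr) {
    p <- transform_points(tr, pts0)
    res <- .cpp_bvh_query(fx_tree, p)
    keep <- rep(TRUE, nrow(p))
    if (params$boundary_reject) keep <- keep & !fx_boundary[res$face]
    d <- res$distance
    if (params$trim_fraction > 0) {
      cutoff <- quantile(d[keep], 1 - params$trim_fraction, names = FALSE, type = 7)
      keep <- keep & d <= cutoff
    }
    list(p = p, q = res$point, n = fx_normals[res$face, , drop = FALSE],
         d = d, keep = keep)
  }

  for (it in seq_len(params$max_iterations)) {
    co <- correspond(total)
    n_keep <- sum(co$keep)
    if (n_keep < params$min_pairs) {
      stop(sprintf("insufficient overlap: %d surviving pairs (< %d) at iteration %d",
                   n_keep, params$min_pairs, it), call. = FALSE)
    }
    rms <- sqrt(mean(co$d[co$keep]^2))
    rms_history <- c(rms_history, rms)
    pairs_used <- n_keep

    if (rms < params$tolerance_mm * 1e-5 ||
        abs(prev_rms - rms) < params$convergence_eps_mm) {
      converged <- TRUE
      break
    }
    prev_rms <- rms

    p <- co$p[co$keep, , drop = FALSE]
    q <- co$q[co$keep, , drop = FALSE]
    nn <- co$n[co$keep, , drop = FALSE]
    r <- rowSums((p - q) * nn)
    A <- cbind(vec_cross(p, nn), nn)
    AtA <- crossprod(A)
    Atb <- crossprod(A, -r)
    x <- tryCatch(solve(AtA + diag(1e-12, 6), Atb),
                  error = function(e) stop(sprintf("numerical failure in point-to-plane solve at iteration %d", it),
                                           call. = FALSE))
    if (any(!is.finite(x))) {
      stop(sprintf("numerical failure in point-to-plane solve at iteration %d", it),
           call. = FALSE)
    }

    # exponential-map update with halving line search to enforce descent
    step <- 1
    improved <- FALSE
    for (ls in 1:6) {
      upd <- twist_transform(x[1:3] * step, x[4:6] * step)
      cand <- compose_transforms(upd, total)
      co2 <- correspond(cand)
      if (sum(co2$keep) >= params$min_pairs) {
        rms2 <- sqrt(mean(co2$d[co2$keep]^2))
        if (rms2 <= rms + 1e-12) {
          total <- cand
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- TRUE
      break
    }
  }

  report <- structure(list(iterations_run = length(rms_history),
                           rms_history = rms_history,
                           pairs_used_final = pairs_used,
                           converged = converged),
                      class = "icp_report")
  list(transform = total, report = report)
}

#' @export
print.icp_report <- function(x, ...) {
  cat(sprintf("<icp_report> %d iterations, final RMS %.3g mm, %d pairs, converged: %s\n",
              x$iterations_run, tail(x$rms_history, 1), x$pairs_used_final,
              x$converged))
  invisible(x)
}

# rigid transform from a twist (rotation vector omega in radians, translation t)
twist_transform <- function(omega, trans) {
  th <- sqrt(sum(omega^2))
  R <- if (th < 1e-12) diag(3) else rotation_about_axis(omega / th, th * 180 / pi)
  rigid_transform(R, as.numeric(trans))
}

#' Superimpose a serial model pair with one of five techniques
#'
#' Dispatches the five reference choices: `3P` (three-point landmark
#' registration on the infraorbital/mastoid triple), `1Z` (ICP on the left
#' zygomatic arch), `BZ` (both arches), `AC` (anterior cranial base) and
#' `ACF` (anterior cranial base + foramen magnum rim). All ICP routes run
#' [coarse_align()] first. The returned transform maps the T1 (moving)
#' frame onto the T0 (reference) frame.
#'
#' @param technique One of `"3P"`, `"1Z"`, `"BZ"`, `"AC"`, `"ACF"`.
#' @param t0,t1 Bundles: lists with `mesh`, `landmarks` (picked, in that
#'   scan's frame) and `atlas` (region descriptors in that frame).
#' @param params An [icp_params()].
#' @return List with `transform` and `report` (`NULL` for `3P`).
#' @export
superimpose <- function(technique = c("3P", "1Z", "BZ", "AC", "ACF"),
                        t0, t1, params = icp_params()) {
  technique <- match.arg(technique)
  if (technique == "3P") {
    need <- c("InfraorbitalL", "InfraorbitalR", "MastoidL")
    tr <- kabsch_3p(t1$landmarks[need, , drop = FALSE],
                    t0$landmarks[need, , drop = FALSE])
    return(list(transform = tr, report = NULL))
  }
  regions <- switch(technique,
                    "1Z" = "ZygomaticArchL",
                    "BZ" = c("ZygomaticArchL", "ZygomaticArchR"),
                    "AC" = "AnteriorCranialBase",
                    "ACF" = c("AnteriorCranialBase", "ForamenMagnumRim"))
  mask_for <- function(msh, atlas) {
    ids <- unlist(lapply(regions, function(r) select_region(msh, atlas[[r]], r)$face_ids))
    region_mask(sort(unique(ids)), paste(regions, collapse = "+"))
  }
  m0 <- mask_for(t0$mesh, t0$atlas)
  m1 <- mask_for(t1$mesh, t1$atlas)
  init <- coarse_align(t1$landmarks, t0$landmarks)
  icp_point_to_plane(moving = t1$mesh, fixed = t0$mesh,
                     moving_mask = m1, fixed_mask = m0,
                     init = init, params = params)
}
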