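# Analytic solids (signed distance functions).
#
# The phantom is a union of posed primitives, each described by a signed
# distance function (negative inside). Rasterisation evaluates these
# distances at voxel centres; region descriptors reuse the same machinery
# for membership tests. Distances are exact for box/sphere/cylinder and
# accurate near the surface for the varying-radius arc tube.

prim_box <- function(half) {
  half <- as.numeric(half)
  list(
    type = "box", params = list(half = half),
    sdf = function(p) {
      q <- abs(p) - rep(half, each = nrow(p))
      qp <- pmax(q, 0)
      outside <- sqrt(rowSums(qp^2))
      inside <- pmin(pmax(q[, 1], q[, 2], q[, 3]), 0)
      outside + inside
    },
    bbox = rbind(-half, half)
  )
}

prim_sphere <- function(radius) {
  list(
    type = "sphere", params = list(radius = radius),
    sdf = function(p) sqrt(rowSums(p^2)) - radius,
    bbox = rbind(rep(-radius, 3), rep(radius, 3))
  )
}

# capped cylinder along local z, half-height h
prim_cylinder <- function(radius, half_height) {
  list(
    type = "cylinder", params = list(radius = radius, half_height = half_height),
    sdf = function(p) {
      dr <- sqrt(p[, 1]^2 + p[, 2]^2) - radius
      dz <- abs(p[, 3]) - half_height
      outside <- sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
      inside <- pmin(pmax(dr, dz), 0)
      outside + inside
    },
    bbox = rbind(c(-radius, -radius, -half_height), c(radius, radius, half_height))
  )
}

# tube around a circular arc in the local xy-plane, centred at the origin.
# arc radius R over angles [a0, a1] (radians); tube radius may undulate with
# angle (r(phi) = r0 + r_amp * sin(r_freq * phi + r_phase)) so that sliding
# along the arc is not a symmetry of the solid.
prim_arc <- function(R, a0, a1, r0, r_amp = 0, r_freq = 0, r_phase = 0) {
  rmax <- r0 + abs(r_amp)
  list(
    type = "arc",
    params = list(R = R, a0 = a0, a1 = a1, r0 = r0, r_amp = r_amp,
                  r_freq = r_freq, r_phase = r_phase),
    sdf = function(p) {
      phi <- atan2(p[, 2], p[, 1])
      mid <- (a0 + a1) / 2
      phi <- phi + 2 * pi * round((mid - phi) / (2 * pi))
      phi <- pmin(pmax(phi, a0), a1)
      cx <- R * cos(phi)
      cy <- R * sin(phi)
      rt <- r0 + r_amp * sin(r_freq * phi + r_phase)
      sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2 + p[, 3]^2) - rt
    },
    bbox = rbind(c(-(R + rmax), -(R + rmax), -rmax),
                 c(R + rmax, R + rmax, rmax))
  )
}

# rebuild a primitive with linear extents scaled by s (used by the operator
# region-extent perturbation model)
scale_prim <- function(prim, s) {
  p <- prim$params
  switch(prim$type,
    box = prim_box(p$half * s),
    sphere = prim_sphere(p$radius * s),
    cylinder = prim_cylinder(p$radius * s, p$half_height * s),
    arc = prim_arc(p$R, p$a0, p$a1, p$r0 * s, p$r_amp * s, p$r_freq, p$r_phase),
    stop("unknown primitive type: ", prim$type)
  )
}

# a primitive with a rigid pose (local -> world)
posed <- function(prim, translation = c(0, 0, 0), rotation = diag(3)) {
  list(prim = prim, pose = rigid_transform(rotation, translation))
}

# a named rigid piece of the phantom: union of positive solids minus union
# of negative solids, carried by a piece-level pose that treatment and
# rescan update
piece_solid <- function(name, pos, neg = list(), pose = identity_transform()) {
  structure(list(name = name, pos = pos, neg = neg, pose = pose),
            class = "cr_piece")
}

piece_sdf <- function(piece, pts_world) {
  local <- transform_points(invert_transform(piece$pose), pts_world)
  eval_group <- function(solids) {
    d <- rep(Inf, nrow(local))
    for (s in solids) {
      pl <- transform_points(invert_transform(s$pose), local)
      d <- pmin(d, s$prim$sdf(pl))
    }
    d
  }
  d <- eval_group(piece$pos)
  if (length(piece$neg)) d <- pmax(d, -eval_group(piece$neg))
  d
}

# world-space axis-aligned bounding box of a piece (conservative)
piece_bbox <- function(piece, margin = 0) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (s in piece$pos) {
    bb <- s$prim$bbox
    corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
    w <- transform_points(piece$pose, transform_points(s$pose, corners))
    lo <- pmin(lo, apply(w, 2, min))
    hi <- pmax(hi, apply(w, 2, max))
  }
  rbind(lo - margin, hi + margin)
}

# membership of world points in a piece/region solid
solid_contains <- function(piece, pts_world, tol = 1e-6) {
  piece_sdf(piece, pts_world) <= tol
}

# rasterise a list of pieces onto a voxel grid; returns the scene signed
# distance at each voxel centre (Inf far from every piece)
rasterize_scene <- function(pieces, dims, spacing, origin) {
  d <- array(Inf, dim = dims)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  for (pc in pieces) {
    bb <- piece_bbox(pc, margin = 2 * max(spacing))
    ix <- which(xs >= bb[1, 1] & xs <= bb[2, 1])
    iy <- which(ys >= bb[1, 2] & ys <= bb[2, 2])
    iz <- which(zs >= bb[1, 3] & zs <= bb[2, 3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = xs[ix], y = ys[iy], z = zs[iz]))
    dv <- piece_sdf(pc, pts)
    sub <- array(dv, dim = c(length(ix), length(iy), length(iz)))
    d[ix, iy, iz] <- pmin(d[ix, iy, iz], sub)
  }
  d
}
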