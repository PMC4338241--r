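# Fixtures built in code: analytic volumes and small meshes.

# volume sampling a ball of given radius: intensity ramps linearly across a
# `ramp_vox`-voxel shell (0 = hard binary)
ball_volume <- function(radius = 20, vox = 0.8, bone = 1200, ramp_vox = 2,
                        pad = 5) {
  n <- ceiling(2 * (radius + pad) / vox)
  xs <- (seq_len(n) - 1) * vox
  ctr <- max(xs) / 2
  g <- expand.grid(x = xs, y = xs, z = xs)
  d <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2) - radius
  cov <- if (ramp_vox > 0) {
    pmin(pmax(0.5 - d / (ramp_vox * vox), 0), 1)
  } else {
    as.numeric(d < 0)
  }
  v <- volume(array(bone * cov, dim = c(n, n, n)), spacing_mm = rep(vox, 3))
  attr(v, "center") <- rep(ctr, 3)
  v
}

sphere_fixture <- function(radius = 20, vox = 0.8, threshold = 600) {
  v <- ball_volume(radius = radius, vox = vox)
  m <- extract_isosurface(v, threshold)
  attr(m, "center") <- attr(v, "center")
  m
}

# unit tetrahedron mesh
tetra_mesh <- function() {
  mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
       rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L), c(2L, 3L, 4L)))
}

# flat rectangular plate in the z = z0 plane, regular triangulation
plate_mesh <- function(nx = 20, ny = 20, step = 1, z0 = 0) {
  xs <- (0:(nx - 1)) * step
  ys <- (0:(ny - 1)) * step
  g <- as.matrix(expand.grid(x = xs, y = ys))
  v <- cbind(g, z0)
  idx <- function(i, j) (j - 1) * nx + i
  f <- list()
  for (j in 1:(ny - 1)) {
    for (i in 1:(nx - 1)) {
      f[[length(f) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
      f[[length(f) + 1]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  mesh(v, do.call(rbind, f))
}

# small coarse sphere mesh (kept under 200 faces) for exhaustive oracles
small_sphere_mesh <- function(radius = 10) {
  m <- sphere_fixture(radius = radius, vox = radius / 1.3, threshold = 600)
  stopifnot(nrow(m$faces) <= 200)
  m
}

# moderate-resolution sphere (~400 faces): still brute-forceable, smooth
# enough for surface-patch fixtures
med_sphere_mesh <- function(radius = 10) {
  sphere_fixture(radius = radius, vox = radius / 2.2, threshold = 600)
}

# ball with three asymmetric surface bumps: a compact solid with no rigid
# self-symmetry, the standard fixture for registration tests
bumpy_ball_mesh <- function(radius = 15, vox = 0.8) {
  v <- ball_volume(radius = radius, vox = vox)
  ctr <- attr(v, "center")
  xs <- (seq_len(dim(v$intensities)[1]) - 1) * vox
  g <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  bumps <- list(c(0, radius - 3, radius - 4), c(radius - 4, 0, -(radius - 5)),
                c(-(radius - 5), radius - 6, 2))
  hu <- as.vector(v$intensities)
  for (b in bumps) {
    d <- sqrt(rowSums(sweep(g, 2, ctr + b)^2)) - 4
    hu <- pmax(hu, 1200 * pmin(pmax(0.5 - d / (2 * vox), 0), 1))
  }
  m <- extract_isosurface(volume(array(hu, dim = dim(v$intensities)),
                                 spacing_mm = rep(vox, 3)), 600)
  attr(m, "center") <- ctr
  m
}

# a quick low-resolution phantom spec for tests that need the full anatomy
fast_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(seed = seed, ...)
}
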