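test_that("three-point registration recovers a known rigid motion exactly", {
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 2))
  rownames(src) <- c("a", "b", "c")
  tr_true <- rigid_transform(rotation_about_axis(c(1, 1, 0), 23), c(3, -2, 5))
  tgt <- transform_points(tr_true, src)
  tr <- kabsch_3p(src, tgt)
  expect_lt(max(abs(tr$rotation - tr_true$rotation)), 1e-9)
  expect_lt(max(abs(tr$translation - tr_true$translation)), 1e-9)

  id <- kabsch_3p(src, src)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_error(kabsch_3p(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), src),
               "degenerate")
})

test_that("Kabsch is optimal against a random-transform oracle under jitter", {
  set.seed(31)
  src <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 8, 2))
  tgt <- src + matrix(rnorm(9, sd = 0.5), 3)
  fit <- kabsch_3p(src, tgt)
  rms <- function(tr) sqrt(mean(rowSums((transform_points(tr, src) - tgt)^2)))
  best_random <- min(replicate(10000, rms(random_rigid_transform(180, 2))))
  expect_lte(rms(fit), best_random)
})

test_that("coarse alignment is exact for congruent landmark sets", {
  lm <- rbind(InfraorbitalL = c(36, 78, 55), InfraorbitalR = c(64, 78, 55),
              MastoidL = c(34, 36, 51.5), Other = c(0, 0, 0))
  self <- coarse_align(lm, lm)
  expect_lt(transform_angle_deg(self), 1e-9)
  expect_lt(transform_translation_norm(self), 1e-9)

  rot <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(0, 0, 0))
  moved <- transform_points(rot, lm)
  rownames(moved) <- rownames(lm)
  rec <- coarse_align(moved, lm)
  expect_equal(transform_angle_deg(rec), 30, tolerance = 1e-6)

  expect_error(coarse_align(lm[1:2, ], lm), "MastoidL")
})

test_that("closest point: exact hits and analytic distances", {
  pl <- plate_mesh(10, 10)
  hit <- closest_point(pl, c(3, 4, 0))
  expect_lt(hit$distance, 1e-12)
  above <- closest_point(pl, c(3.5, 4.5, 2.5))
  expect_equal(above$distance, 2.5, tolerance = 1e-12)
  expect_equal(as.numeric(above$point), c(3.5, 4.5, 0), tolerance = 1e-12)
})

test_that("accelerated closest point equals exhaustive scans (C++ and R oracles)", {
  s <- small_sphere_mesh(radius = 10)
  expect_lte(nrow(s$faces), 400)
  set.seed(5)
  q <- matrix(rnorm(3000, mean = attr(s, "center")[1], sd = 12), ncol = 3)
  fast <- cranioreg:::.cpp_closest_point(s$vertices, s$faces, q)
  slow <- cranioreg:::.cpp_closest_point_exhaustive(s$vertices, s$faces, q)
  expect_identical(fast$face, slow$face)
  expect_equal(fast$distance, slow$distance, tolerance = 1e-12)
  expect_equal(fast$point, slow$point, tolerance = 1e-12)

  # independent plain-R brute force on a subset
  qr <- q[1:25, , drop = FALSE]
  ora <- cranioreg:::closest_point_bruteforce_R(s, qr)
  expect_equal(fast$distance[1:25], ora$distance, tolerance = 1e-9)
})

test_that("boundary flags mark faces on the edge of the active surface", {
  pl <- plate_mesh(10, 10)
  res_border <- closest_point(pl, c(0.1, 0.1, 1), boundary = TRUE)
  expect_true(res_border$is_boundary)
  res_center <- closest_point(pl, c(4.5, 4.5, 1), boundary = TRUE)
  expect_false(res_center$is_boundary)
})

test_that("point-to-plane ICP recovers a rigid displacement of a duplicated mesh", {
  fixed <- bumpy_ball_mesh(radius = 15)
  ctr <- attr(fixed, "center")

  tf <- compose_transforms(rigid_transform(translation = c(2, -3, 1.5)),
                           rotation_about_point(c(0.2, 1, 0.4), 5, ctr))
  moving <- transform_mesh(fixed, tf)
  # coarse init: the inverse displacement known only approximately
  # (0.5 deg / 0.4 mm off), the quality a landmark pre-alignment delivers
  init <- compose_transforms(
    compose_transforms(rigid_transform(translation = c(0.2, -0.3, 0.2)),
                       rotation_about_point(c(1, 0, 0), 0.5, ctr)),
    invert_transform(tf))
  res <- icp_point_to_plane(moving, fixed, init = init,
                            params = icp_params(sample_count = 3000, seed = 2))
  err <- compose_transforms(res$transform, tf)
  expect_lt(transform_angle_deg(err), 0.05)
  expect_lt(transform_translation_norm(err), 0.02)

  # trimmed RMS is non-increasing (within slack)
  expect_true(all(diff(res$report$rms_history) <= 1e-9))

  # starting at the ground truth is a fixed point
  res2 <- icp_point_to_plane(moving, fixed, init = invert_transform(tf),
                             params = icp_params(sample_count = 3000, seed = 2))
  expect_lte(res2$report$iterations_run, 2)
  delta <- compose_transforms(res2$transform, tf)
  expect_lt(transform_angle_deg(delta), 1e-7)
  expect_lt(transform_translation_norm(delta), 1e-7)
})

test_that("ICP is equivariant under a common rotation of both meshes", {
  fixed <- bumpy_ball_mesh(radius = 10, vox = 1)
  ctr <- attr(fixed, "center")
  tf <- compose_transforms(rigid_transform(translation = c(1, 1, 0)),
                           rotation_about_point(c(0, 0, 1), 3, ctr))
  moving <- transform_mesh(fixed, tf)
  p <- icp_params(sample_count = 2000, seed = 4)
  base <- icp_point_to_plane(moving, fixed, params = p)$transform

  Q <- rigid_transform(rotation_about_axis(c(1, 0, 0), 40), c(5, 0, -2))
  conj <- icp_point_to_plane(transform_mesh(moving, Q),
                             transform_mesh(fixed, Q), params = p)$transform
  expected <- compose_transforms(Q, compose_transforms(base, invert_transform(Q)))
  delta <- compose_transforms(conj, invert_transform(expected))
  expect_lt(transform_angle_deg(delta), 0.05)
  expect_lt(transform_translation_norm(delta), 0.05)
})

test_that("trimming makes the registration robust to outlier spikes", {
  fixed <- bumpy_ball_mesh(radius = 15)
  ctr <- attr(fixed, "center")
  tf <- compose_transforms(rigid_transform(translation = c(1, 0.5, -1)),
                           rotation_about_point(c(0, 1, 0), 2, ctr))
  moving <- transform_mesh(fixed, tf)
  init <- invert_transform(tf)
  init$translation <- init$translation + c(0.3, -0.2, 0.2)

  p <- icp_params(sample_count = 3000, trim_fraction = 0.1, seed = 6)
  clean_tr <- icp_point_to_plane(moving, fixed, init = init, params = p)$transform

  # 5% of vertices displaced as a clustered outward artifact blob (the
  # mesh-level analog of a metal artifact present in only one scan)
  spiky <- moving
  n_spike <- ceiling(0.05 * nrow(spiky$vertices))
  seedp <- spiky$vertices[1, ]
  ord <- order(rowSums(sweep(spiky$vertices, 2, seedp)^2))
  idx <- ord[seq_len(n_spike)]
  out_dir <- (seedp - ctr) / sqrt(sum((seedp - ctr)^2))
  spiky$vertices[idx, ] <- spiky$vertices[idx, ] +
    matrix(out_dir, nrow = n_spike, ncol = 3, byrow = TRUE) * 3
  spike_tr <- icp_point_to_plane(spiky, fixed, init = init, params = p)$transform
  expect_lt(sqrt(sum((spike_tr$translation - clean_tr$translation)^2)), 0.05)
})

test_that("insufficient overlap raises a contract error", {
  pl <- plate_mesh(10, 10)
  far <- transform_mesh(pl, rigid_transform(translation = c(1000, 0, 0)))
  expect_error(
    icp_point_to_plane(far, pl,
                       params = icp_params(sample_count = 500, min_pairs = 50,
                                           boundary_reject = TRUE)),
    "insufficient overlap")
})

test_that("masked registration converges using only the masked overlap", {
  pl <- plate_mesh(40, 40, step = 0.5)
  # add mild relief so in-plane motion is observable
  pl$vertices[, 3] <- 0.3 * sin(pl$vertices[, 1]) * cos(pl$vertices[, 2])
  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 1), c(0.4, -0.3, 0.2))
  moving <- transform_mesh(pl, tf)
  half <- region_mask(which(face_centroids(pl)[, 1] < 10), "half")
  res <- icp_point_to_plane(moving, pl, moving_mask = half, fixed_mask = half,
                            params = icp_params(sample_count = 2000, seed = 3))
  expect_gte(res$report$pairs_used_final, 50)
  err <- compose_transforms(res$transform, tf)
  expect_lt(transform_translation_norm(err), 0.05)
})
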