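spec0 <- phantom_spec(noise_sd_hu = 0, partial_volume = FALSE, seed = 11)

test_that("noiseless binary rasterization yields exactly two intensities", {
  ph <- build_phantom(spec0)
  u <- sort(unique(as.vector(ph$volume$intensities)))
  expect_identical(u, c(spec0$background_hu, spec0$bone_hu))
})

test_that("phantom construction is bit-identical under a fixed seed", {
  spec <- phantom_spec(seed = 5)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$landmarks_t0, b$truth$landmarks_t0)
})

test_that("rasterized ball volume matches the analytic sphere volume within 2%", {
  r <- 20
  vox <- 0.8
  v <- ball_volume(radius = r, vox = vox, ramp_vox = 0)
  count <- sum(v$intensities > 0)
  expect_equal(count * vox^3, 4 / 3 * pi * r^3, tolerance = 0.02)
})

test_that("grid too small for the margin is rejected", {
  expect_error(build_phantom(phantom_spec(grid_shape = c(40, 40, 40))),
               "margin")
})

test_that("treatment moves the piriform landmarks apart by exactly the expansion", {
  spec <- phantom_spec(noise_sd_hu = 0, seed = 3)
  ph <- build_phantom(spec)
  tr <- apply_treatment(ph, spec)
  gap0 <- dist(ph$truth$landmarks_t0[c("PiriformL", "PiriformR"), ])[1]
  gap1 <- dist(tr$truth$landmarks_t1[c("PiriformL", "PiriformR"), ])[1]
  expect_equal(gap1 - gap0, spec$expansion_total_mm, tolerance = 1e-12)
  # form-stable structures never move
  stable <- c("SellaPatchCenter", "ForamenPatchCenterR", "ForamenPatchCenterL",
              "InfraorbitalL", "InfraorbitalR", "MastoidL")
  expect_true(all(abs(tr$truth$true_displacements[stable, ]) == 0))
})

test_that("null treatment leaves the solid voxel-identical (noise resampled)", {
  spec <- phantom_spec(noise_sd_hu = 0, expansion_total_mm = 0,
                       zygoma_bend_deg = 0, seed = 9)
  ph <- build_phantom(spec)
  tr <- apply_treatment(ph, spec)
  expect_identical(tr$volume$intensities, ph$volume$intensities)
  expect_equal(tr$truth$true_displacements, ph$truth$landmarks_t0 * 0)
})

test_that("rescan with zero bounds is the identity; fixed seed repeats", {
  spec <- phantom_spec(noise_sd_hu = 0, rescan_rotation_max_deg = 0,
                       rescan_translation_max_mm = 0, seed = 4)
  ph <- build_phantom(spec)
  rs <- simulate_rescan(ph$volume, spec)
  expect_lt(transform_angle_deg(rs$transform), 1e-12)
  expect_lt(transform_translation_norm(rs$transform), 1e-12)
  expect_identical(rs$volume$intensities, ph$volume$intensities)

  spec2 <- phantom_spec(seed = 4)
  ph2 <- build_phantom(spec2)
  a <- simulate_rescan(ph2$volume, spec2, seed = 99)
  b <- simulate_rescan(ph2$volume, spec2, seed = 99)
  expect_identical(a$transform, b$transform)
})

test_that("ground truth composes exactly: landmarks_t1 = rescan(treatment(landmarks_t0))", {
  spec <- phantom_spec(seed = 21)
  pat <- make_patient(spec)
  tru <- pat$truth
  for (nm in rownames(tru$landmarks_t0)) {
    pc <- tru$landmark_piece[nm]
    expected <- transform_points(
      compose_transforms(tru$rescan_transform, tru$piece_transforms[[pc]]),
      tru$landmarks_t0[nm, ])
    expect_equal(unname(tru$landmarks_t1[nm, ]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("operator jitter: sd 0 is identity; jitter is unbiased; picks land on the surface", {
  pl <- plate_mesh(40, 40, step = 1, z0 = 0)
  lms <- cbind(runif(8, 10, 25), runif(8, 10, 25), 0)
  rownames(lms) <- paste0("p", 1:8)
  spec <- phantom_spec(seed = 2)
  atlas <- build_phantom(spec)$atlas

  out0 <- jitter_operator(lms, atlas, 0)
  expect_identical(out0$landmarks, lms)
  expect_identical(out0$atlas, atlas)

  # Monte-Carlo unbiasedness of the in-plane components (the projection onto
  # the plate removes the z component): 10^4 draws
  big <- lms[rep(1, 10000), , drop = FALSE]
  rownames(big) <- NULL
  out <- jitter_operator(big, atlas, 0.5, pl, seed = 77)
  for (ax in 1:2) {
    dev <- out$landmarks[, ax] - big[, ax]
    expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
  }
  # projection contract: every pick lies on the mesh surface
  cp <- closest_point(pl, out$landmarks[1:100, ])
  expect_lt(max(cp$distance), 1e-9)
})

test_that("atlas regions ride their pieces into the T1 frame", {
  spec <- phantom_spec(seed = 13)
  pat <- make_patient(spec)
  at1 <- atlas_in_t1(pat$atlas, pat$truth)
  # form-stable region: pose differs from T0 exactly by the rescan
  expected <- compose_transforms(pat$truth$rescan_transform,
                                 pat$atlas$AnteriorCranialBase$pose)
  expect_equal(at1$AnteriorCranialBase$pose$rotation, expected$rotation,
               tolerance = 1e-12)
  expect_equal(at1$AnteriorCranialBase$pose$translation, expected$translation,
               tolerance = 1e-12)
})
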