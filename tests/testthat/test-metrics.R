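test_that("patch deviation is zero for identical aligned meshes", {
  pl <- plate_mesh(20, 20)
  patch <- circular_patch(pl, c(9.5, 9.5, 0), 5)
  rec <- patch_deviation(pl, pl, patch)
  expect_equal(rec$D, 0, tolerance = 1e-12)
  expect_equal(c(rec$Dx, rec$Dy, rec$Dz), c(0, 0, 0), tolerance = 1e-12)
})

test_that("a pure offset gives D equal to the offset with the documented sign", {
  pl <- plate_mesh(20, 20)
  patch <- circular_patch(pl, c(9.5, 9.5, 0), 5)
  ref <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 0.5)))
  rec <- patch_deviation(pl, ref, patch)
  expect_equal(rec$D, 0.5, tolerance = 1e-9)
  expect_equal(rec$Dz, -0.5, tolerance = 1e-9)
  expect_equal(c(rec$Dx, rec$Dy), c(0, 0), tolerance = 1e-9)
})

test_that("curved-patch deviation matches a dense brute-force closest-point mean", {
  s <- med_sphere_mesh(radius = 10)
  ctr <- attr(s, "center")
  patch <- circular_patch(s, ctr + c(0, 0, 10), 8, max_dist = 3)
  off <- rigid_transform(translation = c(0.1, -0.2, 0.4))
  ref <- transform_mesh(s, off)
  rec <- patch_deviation(s, ref, patch)
  sp <- cranioreg:::patch_sample_points(s, patch$face_ids)
  ora <- cranioreg:::closest_point_bruteforce_R(ref, sp$points)
  w <- sp$weights / sum(sp$weights)
  expect_equal(rec$D, sum(w * ora$distance), tolerance = 1e-6)
})

test_that("D_accuracy is the mean of the three patch deviations", {
  pl <- plate_mesh(40, 40)
  patches <- lapply(list(c(9.5, 9.5, 0), c(20.5, 20.5, 0), c(30.5, 9.5, 0)),
                    function(ctr) circular_patch(pl, c(ctr[1], ctr[2], 0), 5))
  ref <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 0.3)))
  acc <- accuracy_D(pl, ref, patches)
  expect_equal(acc$D_accuracy, mean(acc$patch_deviations$D), tolerance = 1e-12)
  expect_equal(acc$D_accuracy, 0.3, tolerance = 1e-9)
})

test_that("patch deviation is invariant under a common rigid motion", {
  s <- med_sphere_mesh(radius = 10)
  ctr <- attr(s, "center")
  patch <- circular_patch(s, ctr + c(0, 0, 10), 8, max_dist = 3)
  ref <- transform_mesh(s, rigid_transform(translation = c(0.2, 0.1, -0.3)))
  base <- patch_deviation(s, ref, patch)$D
  Q <- rigid_transform(rotation_about_axis(c(1, 2, 3), 33), c(4, -5, 6))
  moved <- patch_deviation(transform_mesh(s, Q), transform_mesh(ref, Q), patch)$D
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("plate-patch deviation increases strictly with the offset", {
  pl <- plate_mesh(20, 20)
  patch <- circular_patch(pl, c(9.5, 9.5, 0), 5)
  ds <- sapply(c(0.1, 0.3, 0.7, 1.2), function(dz) {
    ref <- transform_mesh(pl, rigid_transform(translation = c(0, 0, dz)))
    patch_deviation(pl, ref, patch)$D
  })
  expect_true(all(diff(ds) > 0))
})

test_that("correspondence failure beyond 10 mm raises the grey-zone error", {
  pl <- plate_mesh(10, 10)
  patch <- circular_patch(pl, c(4.5, 4.5, 0), 5)
  ref <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 50)))
  expect_error(patch_deviation(pl, ref, patch), "correspondence failure")
})

test_that("landmark displacement follows transform(t1) - t0", {
  expect_equal(landmark_displacement(c(1, 2, 3), c(1, 2, 3),
                                     identity_transform())$D, 0)
  tr <- rigid_transform(translation = c(0.5, 0, 0))
  rec <- landmark_displacement(c(0, 0, 0), c(1, 1, 1), tr)
  expect_equal(c(rec$Dx, rec$Dy, rec$Dz), c(1.5, 1, 1))
  expect_equal(rec$D, sqrt(1.5^2 + 2), tolerance = 1e-12)
})

test_that("deviation field: zeros on identity, signed uniform offset, NA beyond cutoff", {
  pl <- plate_mesh(15, 15)
  f0 <- deviation_field(pl, pl)
  expect_true(all(abs(f0$scalar) < 1e-12))

  up <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 0.5)))
  f1 <- deviation_field(up, pl)
  inner <- which(up$vertices[, 1] > 2 & up$vertices[, 1] < 12 &
                   up$vertices[, 2] > 2 & up$vertices[, 2] < 12)
  expect_true(all(abs(f1$scalar[inner] - 0.5) < 1e-9))

  far <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 30)))
  f2 <- deviation_field(far, pl)
  expect_true(all(is.na(f2$scalar)))
})

test_that("deviation field means agree with patch deviation records", {
  pl <- plate_mesh(20, 20)
  patch <- circular_patch(pl, c(9.5, 9.5, 0), 10)
  ref <- transform_mesh(pl, rigid_transform(translation = c(0, 0, 0.4)))
  fld <- deviation_field(pl, ref)
  verts <- unique(as.vector(pl$faces[patch$face_ids, ]))
  expect_equal(mean(abs(fld$scalar[verts])),
               patch_deviation(pl, ref, patch)$D, tolerance = 0.02)
})

test_that("trim_to_roi keeps inside faces, flags empties, and halves a sphere", {
  s <- sphere_fixture(radius = 10, vox = 1)
  ctr <- attr(s, "center")
  big <- rbind(ctr - 100, ctr + 100)
  expect_identical(nrow(trim_to_roi(s, big)$faces), nrow(s$faces))

  none <- trim_to_roi(s, rbind(c(-10, -10, -10), c(-5, -5, -5)))
  expect_identical(nrow(none$faces), 0L)
  expect_true(attr(none, "empty"))

  half <- trim_to_roi(s, rbind(c(-100, -100, ctr[3]), ctr + 100))
  expect_equal(nrow(half$faces) / nrow(s$faces), 0.5, tolerance = 0.1)
})
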