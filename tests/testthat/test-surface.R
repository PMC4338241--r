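test_that("isosurface of a sampled ball matches the analytic sphere", {
  r <- 20
  v <- ball_volume(radius = r, vox = 0.8)
  m <- extract_isosurface(v, 500)
  # area oracle: 4 pi r^2 within 2% (threshold 500 sits slightly off the
  # ramp midpoint, displacing the surface outward by a known sub-voxel bias)
  expect_equal(mesh_area(m), 4 * pi * r^2, tolerance = 0.02)
  # closed surface: sphere topology, no boundary edges, outward orientation
  expect_identical(euler_characteristic(m), 2L)
  expect_identical(count_boundary_edges(m), 0L)
  expect_gt(mesh_signed_volume(m), 0)
})

test_that("isosurface position converges at first order in voxel size", {
  r <- 12
  err <- sapply(c(0.8, 0.4), function(vox) {
    v <- ball_volume(radius = r, vox = vox)
    m <- extract_isosurface(v, 600)
    ctr <- attr(v, "center")
    mean(abs(sqrt(rowSums(sweep(m$vertices, 2, ctr)^2)) - r))
  })
  expect_lte(err[2], err[1] / 2 + 1e-6)
})

test_that("thresholds in the same intensity gap cross the same voxel edges", {
  v <- ball_volume(radius = 10, vox = 0.8, ramp_vox = 0)  # binary phantom
  m300 <- extract_isosurface(v, 300)
  m500 <- extract_isosurface(v, 500)
  expect_identical(dim(m300$faces), dim(m500$faces))
  expect_identical(m300$faces, m500$faces)
})

test_that("degenerate thresholds are rejected", {
  v <- ball_volume(radius = 10, vox = 1)
  expect_error(extract_isosurface(v, 5000), "threshold")
  empty <- volume(array(0, dim = c(8, 8, 8)))
  expect_error(extract_isosurface(empty, 400), "threshold")
})

test_that("clean_components removes floaters but keeps the main component and ties", {
  s <- sphere_fixture(radius = 10, vox = 1)
  expect_identical(clean_components(s)$faces, s$faces)

  # sphere + 10-triangle floater
  fl <- plate_mesh(4, 3, step = 0.5, z0 = 60)
  fl <- mesh(fl$vertices, fl$faces[1:10, , drop = FALSE])
  combo <- mesh(rbind(s$vertices, fl$vertices),
                rbind(s$faces, fl$faces + nrow(s$vertices)))
  cleaned <- clean_components(combo, 0.01)
  expect_identical(nrow(cleaned$faces), nrow(s$faces))

  # two equal components are both retained (tie is not below threshold)
  twin <- mesh(rbind(s$vertices, s$vertices + 100),
               rbind(s$faces, s$faces + nrow(s$vertices)))
  expect_identical(nrow(clean_components(twin, 0.5)$faces), 2L * nrow(s$faces))
})

test_that("decimation honors the budget and preserves area", {
  s <- sphere_fixture(radius = 20, vox = 0.8)
  expect_identical(decimate_to_budget(s, nrow(s$faces) + 1), s)

  d <- decimate_to_budget(s, 2000)
  expect_lte(nrow(d$faces), 2000)
  expect_equal(mesh_area(d), mesh_area(s), tolerance = 0.05)
  expect_true(is.finite(attr(d, "decimation_drift_mm")))

  tiny <- decimate_to_budget(sphere_fixture(radius = 5, vox = 1), 4)
  expect_lte(nrow(tiny$faces), 4)
})

test_that("select_region follows the face-centroid membership rule", {
  s <- sphere_fixture(radius = 10, vox = 0.8)
  ctr <- attr(s, "center")
  v1 <- s$vertices[1, ]
  ball <- cranioreg:::piece_solid("probe",
    pos = list(cranioreg:::posed(cranioreg:::prim_sphere(5), v1)))
  mask <- select_region(s, ball, "probe")
  cen <- face_centroids(s)[mask$face_ids, , drop = FALSE]
  expect_lte(max(sqrt(rowSums(sweep(cen, 2, v1)^2))), 5 + 1e-6)

  whole <- cranioreg:::piece_solid("all",
    pos = list(cranioreg:::posed(cranioreg:::prim_box(c(50, 50, 50)), ctr)))
  expect_identical(select_region(s, whole, "all")$face_ids,
                   seq_len(nrow(s$faces)))

  off <- cranioreg:::piece_solid("miss",
    pos = list(cranioreg:::posed(cranioreg:::prim_sphere(1), ctr + 100)))
  expect_error(select_region(s, off, "miss"), "region miss")
})

test_that("foramen rim region area matches its nominal 1.0 x 1.5 cm extent", {
  ph <- build_phantom(phantom_spec(seed = 8))
  m <- clean_components(extract_isosurface(ph$volume, 400))
  mask <- select_region(m, ph$atlas$ForamenMagnumRim)
  area <- sum(face_areas(m)[mask$face_ids])
  expect_equal(area, 150, tolerance = 0.30)
})

test_that("circular patches grow to the requested area and monotonically nest", {
  pl <- plate_mesh(30, 30, step = 0.5)
  ctr <- c(7.25, 7.25, 0)
  p5 <- circular_patch(pl, ctr, 5)
  a5 <- attr(p5, "achieved_area_mm2")
  max_face <- max(face_areas(pl))
  expect_gte(a5, 5)
  expect_lt(a5, 5 + max_face)

  p15 <- circular_patch(pl, ctr, 15)
  expect_true(all(p5$face_ids %in% p15$face_ids))

  # determinism
  expect_identical(circular_patch(pl, ctr, 5)$face_ids, p5$face_ids)

  expect_error(circular_patch(pl, c(7, 7, 10), 5), "from the surface")
})

test_that("patch on a sphere stays within the analytic geodesic radius", {
  s <- sphere_fixture(radius = 20, vox = 0.8)
  ctr <- attr(s, "center")
  seed_pt <- ctr + c(0, 0, 20)
  p <- circular_patch(s, seed_pt, 5)
  # geodesic radius of a 5 mm^2 cap is ~ sqrt(5/pi); allow one face diameter
  face_diam <- 2 * sqrt(max(face_areas(s)))
  cen <- face_centroids(s)[p$face_ids, , drop = FALSE]
  # chord -> arc length on the sphere
  seed_surf <- closest_point(s, matrix(seed_pt, ncol = 3))$point
  chord <- sqrt(rowSums(sweep(cen, 2, as.numeric(seed_surf))^2))
  arc <- 2 * 20 * asin(pmin(chord / (2 * 20), 1))
  expect_lte(max(arc), sqrt(5 / pi) + 2 * face_diam)
})
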