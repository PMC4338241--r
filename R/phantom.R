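#' Specification of a synthetic skull phantom
#'
#' The phantom stands in for a patient CT pair in the superimposition study.
#' It is a stylised skull: a cranial-base shelf (two joined plates with a
#' sella depression and small surface bumps), a hollow posterior ring
#' (foramen magnum), two slender lateral arcs with undulating thickness
#' (zygomatic arches), and an anterior U-shaped maxilla carrying incisor
#' prongs and a piriform notch. The cranial base and the ring are
#' form-stable; treatment (rapid maxillary expansion) translates the two
#' hemimaxillae apart and bends the arches outward.
#'
#' Defaults follow the emulated acquisition and treatment: 0.8 mm voxels,
#' a total expansion of 9 mm (0.6 mm/day over a 15-day activation), and a
#' rescan repositioning of up to 5 degrees and 4 mm.
#'
#' @param voxel_size_mm Isotropic voxel size (mm), default 0.8.
#' @param grid_shape Grid dimensions (3 positive integers).
#' @param bone_hu,background_hu Intensities of solid and background (HU).
#' @param noise_sd_hu SD of additive Gaussian intensity noise (HU).
#' @param expansion_total_mm Total transverse maxillary expansion (mm).
#' @param zygoma_bend_deg Outward rotation of each zygomatic arch about a
#'   vertical axis through its posterior root (degrees).
#' @param rescan_rotation_max_deg,rescan_translation_max_mm Bounds of the
#'   random rigid repositioning between the two scans.
#' @param partial_volume If `TRUE` (default) boundary voxels take
#'   intermediate intensities over a two-voxel shell, emulating CT
#'   partial-volume averaging (the bone threshold of 300-500 HU cuts within
#'   this ramp, giving sub-voxel surface placement). If `FALSE` every voxel
#'   is exactly `bone_hu` or `background_hu` before noise.
#' @param seed Integer seed fixing all randomness of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size_mm = 0.8,
                         grid_shape = c(140, 140, 110),
                         bone_hu = 1200,
                         background_hu = 0,
                         noise_sd_hu = 50,
                         expansion_total_mm = 9,
                         zygoma_bend_deg = 2,
                         rescan_rotation_max_deg = 5,
                         rescan_translation_max_mm = 4,
                         partial_volume = TRUE,
                         seed = 1L) {
  stopifnot(voxel_size_mm > 0, length(grid_shape) == 3, all(grid_shape >= 8),
            noise_sd_hu >= 0, expansion_total_mm >= 0, zygoma_bend_deg >= 0,
            rescan_rotation_max_deg >= 0, rescan_translation_max_mm >= 0)
  structure(list(voxel_size_mm = voxel_size_mm,
                 grid_shape = as.integer(grid_shape),
                 bone_hu = bone_hu, background_hu = background_hu,
                 noise_sd_hu = noise_sd_hu,
                 expansion_total_mm = expansion_total_mm,
                 zygoma_bend_deg = zygoma_bend_deg,
                 rescan_rotation_max_deg = rescan_rotation_max_deg,
                 rescan_translation_max_mm = rescan_translation_max_mm,
                 partial_volume = isTRUE(partial_volume),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# geometry offset placing the anatomy away from the grid boundary
.PHANTOM_OFFSET <- c(6, 6, 4)

# T0 geometry: pieces, landmarks (with owning piece), and atlas descriptors.
# All coordinates in mm, before the global offset.
phantom_geometry <- function() {
  o <- .PHANTOM_OFFSET
  tr <- function(p) p + o

  pieces <- list(
    base_anterior = piece_solid(
      "base_anterior",
      pos = list(
        posed(prim_box(c(26, 14, 4))),
        # relief bumps on the shelf top: break in-plane sliding symmetry
        posed(prim_sphere(3), c(-12, -6, 3)),
        posed(prim_sphere(3), c(10, 4, 3)),
        posed(prim_sphere(3), c(-6, 8, 3))
      ),
      neg = list(posed(prim_sphere(5), c(0, -10, 6))),   # sella depression
      pose = rigid_transform(translation = tr(c(50, 64, 58)))
    ),
    base_posterior = piece_solid(
      "base_posterior",
      pos = list(posed(prim_box(c(18, 10, 3.5)))),
      pose = rigid_transform(translation = tr(c(50, 42, 55)))
    ),
    foramen_ring = piece_solid(
      "foramen_ring",
      pos = list(posed(prim_cylinder(16, 6))),
      neg = list(posed(prim_cylinder(11, 7))),
      pose = rigid_transform(translation = tr(c(50, 30, 30)))
    ),
    arch_L = piece_solid(
      "arch_L",
      pos = list(posed(prim_arc(22, 120 * pi / 180, 240 * pi / 180,
                                2.5, 0.7, 2.5, 0.4))),
      pose = rigid_transform(translation = tr(c(30, 45, 48)))
    ),
    arch_R = piece_solid(
      "arch_R",
      pos = list(posed(prim_arc(22, -60 * pi / 180, 60 * pi / 180,
                                2.5, 0.7, 2.5, -0.4))),
      pose = rigid_transform(translation = tr(c(70, 45, 48)))
    ),
    maxilla_L = piece_solid(
      "maxilla_L",
      pos = list(
        posed(prim_box(c(10, 8, 10))),                  # hemimaxilla body
        posed(prim_box(c(6, 4, 3)), c(6, 6, -7)),       # anterior bridge half
        posed(prim_cylinder(1.5, 4), c(8, 6, -12))      # incisor prong
      ),
      pose = rigid_transform(translation = tr(c(38, 74, 24)))
    ),
    maxilla_R = piece_solid(
      "maxilla_R",
      pos = list(
        posed(prim_box(c(10, 8, 10))),
        posed(prim_box(c(6, 4, 3)), c(-6, 6, -7)),
        posed(prim_cylinder(1.5, 4), c(-8, 6, -12))
      ),
      pose = rigid_transform(translation = tr(c(62, 74, 24)))
    )
  )

  a25 <- 25 * pi / 180
  lm <- rbind(
    PiriformL = tr(c(48, 78, 26)),
    PiriformR = tr(c(52, 78, 26)),
    IncisorL = tr(c(46, 81.5, 9)),
    IncisorR = tr(c(54, 81.5, 9)),
    InfraorbitalL = tr(c(36, 78, 55)),
    InfraorbitalR = tr(c(64, 78, 55)),
    MastoidL = tr(c(34, 36, 51.5)),
    SellaPatchCenter = tr(c(50, 54, 59)),
    ForamenPatchCenterR = tr(c(50 + 16 * sin(a25), 30 - 16 * cos(a25), 30)),
    ForamenPatchCenterL = tr(c(50 - 16 * sin(a25), 30 - 16 * cos(a25), 30))
  )
  landmark_piece <- c(
    PiriformL = "maxilla_L", PiriformR = "maxilla_R",
    IncisorL = "maxilla_L", IncisorR = "maxilla_R",
    InfraorbitalL = "base_anterior", InfraorbitalR = "base_anterior",
    MastoidL = "base_posterior",
    SellaPatchCenter = "base_anterior",
    ForamenPatchCenterR = "foramen_ring", ForamenPatchCenterL = "foramen_ring"
  )

  atlas <- list(
    AnteriorCranialBase = piece_solid(
      "AnteriorCranialBase", pos = list(posed(prim_box(c(22, 12, 3)))),
      pose = rigid_transform(translation = tr(c(50, 62, 62)))
    ),
    ForamenMagnumRim = piece_solid(
      "ForamenMagnumRim", pos = list(posed(prim_box(c(7.5, 2.5, 5)))),
      pose = rigid_transform(translation = tr(c(50, 14.5, 30)))
    ),
    ZygomaticArchL = piece_solid(
      "ZygomaticArchL",
      pos = list(posed(prim_arc(22, 125 * pi / 180, 235 * pi / 180, 4.5))),
      pose = rigid_transform(translation = tr(c(30, 45, 48)))
    ),
    ZygomaticArchR = piece_solid(
      "ZygomaticArchR",
      pos = list(posed(prim_arc(22, -55 * pi / 180, 55 * pi / 180, 4.5))),
      pose = rigid_transform(translation = tr(c(70, 45, 48)))
    ),
    Maxilla = piece_solid(
      "Maxilla", pos = list(posed(prim_box(c(18, 10, 12)))),
      pose = rigid_transform(translation = tr(c(50, 75, 24)))
    )
  )
  # which rigid piece each atlas region rides on (for mapping to T1)
  atlas_piece <- c(AnteriorCranialBase = "base_anterior",
                   ForamenMagnumRim = "foramen_ring",
                   ZygomaticArchL = "arch_L",
                   ZygomaticArchR = "arch_R",
                   Maxilla = "maxilla_L")  # nominal; maxilla region is not a reference

  # posterior roots of the arches (fixed points of the treatment bend)
  arch_roots <- list(
    arch_L = tr(c(30, 45, 48)) + 22 * c(cos(240 * pi / 180), sin(240 * pi / 180), 0),
    arch_R = tr(c(70, 45, 48)) + 22 * c(cos(-60 * pi / 180), sin(-60 * pi / 180), 0)
  )

  list(pieces = pieces, landmarks = lm, landmark_piece = landmark_piece,
       atlas = atlas, atlas_piece = atlas_piece, arch_roots = arch_roots)
}

rasterize_phantom <- function(pieces, spec, noise_seed) {
  dims <- spec$grid_shape
  sp <- rep(spec$voxel_size_mm, 3)
  org <- c(0, 0, 0)
  # boundary margin check: no primitive may come within 2 voxels of the grid
  extent <- (dims - 1) * sp
  for (pc in pieces) {
    bb <- piece_bbox(pc)
    if (any(bb[1, ] < 2 * sp) || any(bb[2, ] > extent - 2 * sp)) {
      stop(sprintf("grid too small: piece '%s' violates the 2-voxel margin; enlarge grid_shape", pc$name),
           call. = FALSE)
    }
  }
  d <- rasterize_scene(pieces, dims, sp, org)
  if (spec$partial_volume) {
    # intensity ramps linearly across a two-voxel boundary shell, so
    # linear edge interpolation recovers the surface at sub-voxel accuracy
    cov <- pmin(pmax(0.5 - d / (2 * spec$voxel_size_mm), 0), 1)
  } else {
    cov <- as.numeric(d < 0)
  }
  hu <- spec$background_hu + (spec$bone_hu - spec$background_hu) * cov
  if (spec$noise_sd_hu > 0) {
    set.seed(noise_seed)
    hu <- hu + rnorm(length(hu), sd = spec$noise_sd_hu)
  }
  volume(array(hu, dim = dims), spacing_mm = sp, origin_mm = org,
         scene = list(pieces = pieces, spec = spec))
}

child_seed <- function(seed, k) as.integer((as.numeric(seed) * 48271 + k) %% 2147483629)

#' Build the pre-treatment (T0) phantom
#'
#' Rasterises the T0 skull phantom and emits its ground truth (landmarks,
#' per-landmark treatment displacements, rescan transform placeholder) and
#' the reference-region atlas in T0 mm coordinates.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([volume()]), `truth`
#'   (class `cr_ground_truth`) and `atlas` (named list of region
#'   descriptors).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry()
  vol <- rasterize_phantom(geo$pieces, spec, noise_seed = child_seed(spec$seed, 1))
  truth <- structure(list(
    rescan_transform = identity_transform(),
    landmarks_t0 = geo$landmarks,
    landmarks_t1 = geo$landmarks,
    true_displacements = geo$landmarks * 0,
    piece_transforms = setNames(
      replicate(length(geo$pieces), identity_transform(), simplify = FALSE),
      names(geo$pieces)),
    landmark_piece = geo$landmark_piece,
    atlas_piece = geo$atlas_piece,
    arch_roots = geo$arch_roots,
    treatment_applied = FALSE
  ), class = "cr_ground_truth")
  list(volume = vol, truth = truth, atlas = geo$atlas)
}

#' @export
print.cr_ground_truth <- function(x, ...) {
  cat(sprintf("<cr_ground_truth> %d landmarks, treatment %s, rescan %.3f deg / %.3f mm\n",
              nrow(x$landmarks_t0),
              if (x$treatment_applied) "applied" else "not applied",
              transform_angle_deg(x$rescan_transform),
              transform_translation_norm(x$rescan_transform)))
  invisible(x)
}

#' Apply the treatment deformation (rapid maxillary expansion)
#'
#' Piecewise-rigid deformation of the T0 phantom: each hemimaxilla is
#' translated laterally by half the total expansion, each zygomatic arch is
#' rotated outward about a vertical axis through its posterior root, and the
#' cranial base and foramen ring are untouched. Landmark ground truth is
#' updated exactly; noise is resampled for the new volume.
#'
#' @param phantom A list as returned by [build_phantom()].
#' @param spec The [phantom_spec()] used to build it.
#' @return A list like [build_phantom()]'s with the deformed (pre-rescan)
#'   volume and updated truth.
#' @export
apply_treatment <- function(phantom, spec) {
  truth <- phantom$truth
  stopifnot(inherits(truth, "cr_ground_truth"), !truth$treatment_applied)
  pieces <- phantom$volume$scene$pieces
  e2 <- spec$expansion_total_mm / 2
  bend <- spec$zygoma_bend_deg

  tf <- truth$piece_transforms
  tf$maxilla_L <- rigid_transform(translation = c(-e2, 0, 0))
  tf$maxilla_R <- rigid_transform(translation = c(e2, 0, 0))
  tf$arch_L <- rotation_about_point(c(0, 0, 1), bend, truth$arch_roots$arch_L)
  tf$arch_R <- rotation_about_point(c(0, 0, 1), -bend, truth$arch_roots$arch_R)

  moved <- lapply(names(pieces), function(nm) {
    pc <- pieces[[nm]]
    pc$pose <- compose_transforms(tf[[nm]], pc$pose)
    pc
  })
  names(moved) <- names(pieces)

  lm1 <- truth$landmarks_t0
  for (i in seq_len(nrow(lm1))) {
    pc <- truth$landmark_piece[rownames(lm1)[i]]
    lm1[i, ] <- transform_points(tf[[pc]], lm1[i, ])
  }

  vol <- rasterize_phantom(moved, spec, noise_seed = child_seed(spec$seed, 2))
  truth$piece_transforms <- tf
  truth$landmarks_t1 <- lm1
  truth$true_displacements <- lm1 - truth$landmarks_t0
  truth$treatment_applied <- TRUE
  list(volume = vol, truth = truth, atlas = phantom$atlas)
}

#' Simulate the rigid repositioning between scans
#'
#' Samples a rigid transform uniformly within the rescan bounds of `spec` and
#' applies it to the analytic solid before rasterisation (no voxel
#' resampling, so no interpolation artifacts). The transform is returned as
#' ground truth; the caller composes it onto treated landmark positions.
#'
#' @param vol A phantom [volume()] carrying its analytic scene.
#' @param spec The [phantom_spec()].
#' @param seed Integer seed for the transform draw and the noise resample.
#' @return List with `volume` (repositioned rasterisation) and `transform`
#'   (the sampled [rigid_transform()], mapping the old frame to the new).
#' @export
simulate_rescan <- function(vol, spec, seed = child_seed(spec$seed, 3)) {
  stopifnot(!is.null(vol$scene))
  pieces <- vol$scene$pieces
  ctr <- Reduce(`+`, lapply(pieces, function(pc) colMeans(piece_bbox(pc)))) / length(pieces)
  set.seed(seed)
  tf <- random_rigid_transform(spec$rescan_rotation_max_deg,
                               spec$rescan_translation_max_mm, center = ctr)
  moved <- lapply(pieces, function(pc) {
    pc$pose <- compose_transforms(tf, pc$pose)
    pc
  })
  vol2 <- tryCatch(
    rasterize_phantom(moved, spec, noise_seed = child_seed(seed, 4)),
    error = function(e) stop("rescan transform moves the solid outside the grid margin",
                             call. = FALSE)
  )
  list(volume = vol2, transform = tf)
}

#' Generate a complete synthetic patient
#'
#' Convenience wrapper running [build_phantom()], [apply_treatment()] and
#' [simulate_rescan()] so that `landmarks_t1 = rescan(treatment(landmarks_t0))`
#' exactly by construction.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume_t0`, `volume_t1`, `truth` and `atlas`.
#' @export
make_patient <- function(spec) {
  ph <- build_phantom(spec)
  tr <- apply_treatment(ph, spec)
  rs <- simulate_rescan(tr$volume, spec)
  truth <- tr$truth
  truth$rescan_transform <- rs$transform
  truth$landmarks_t1 <- transform_points(rs$transform, tr$truth$landmarks_t1)
  list(volume_t0 = ph$volume, volume_t1 = rs$volume, truth = truth,
       atlas = ph$atlas)
}

#' Map the T0 region atlas into the T1 frame
#'
#' Region descriptors ride on rigid pieces; the T1 descriptor of a region is
#' its T0 descriptor composed with the treatment transform of its piece and
#' the rescan transform.
#'
#' @param atlas Atlas from [build_phantom()].
#' @param truth Ground truth carrying piece transforms and the rescan.
#' @export
atlas_in_t1 <- function(atlas, truth) {
  out <- lapply(names(atlas), function(nm) {
    reg <- atlas[[nm]]
    pc <- truth$atlas_piece[nm]
    tf <- compose_transforms(truth$rescan_transform, truth$piece_transforms[[pc]])
    reg$pose <- compose_transforms(tf, reg$pose)
    reg
  })
  names(out) <- names(atlas)
  out
}

#' Operator variability model
#'
#' Emulates a human operator picking landmarks and outlining reference
#' regions: isotropic Gaussian jitter (SD `sd_mm`) is added to each landmark
#' and the result is re-projected onto the mesh surface; each region
#' descriptor's linear extent is rescaled by a factor drawn uniformly from
#' `1 +/- extent_fraction`.
#'
#' @param landmarks Landmark matrix (rows named, mm).
#' @param atlas Named list of region descriptors.
#' @param sd_mm Landmark jitter SD (mm); 0 disables jitter entirely.
#' @param mesh_obj Mesh the jittered landmarks are projected onto (required
#'   when `sd_mm > 0`).
#' @param extent_fraction Bound of the relative region-extent perturbation
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List with `landmarks` and `atlas`.
#' @export
jitter_operator <- function(landmarks, atlas, sd_mm, mesh_obj = NULL,
                            extent_fraction = 0.2, seed = 1L) {
  stopifnot(sd_mm >= 0)
  if (sd_mm == 0) return(list(landmarks = landmarks, atlas = atlas))
  stopifnot(inherits(mesh_obj, "cr_mesh"))
  set.seed(seed)
  lm <- landmarks + matrix(rnorm(length(landmarks), sd = sd_mm),
                           nrow = nrow(landmarks))
  cp <- closest_point(mesh_obj, lm)
  lm_proj <- cp$point
  dimnames(lm_proj) <- dimnames(landmarks)
  at <- lapply(atlas, function(reg) {
    s <- runif(1, 1 - extent_fraction, 1 + extent_fraction)
    reg$pos <- lapply(reg$pos, function(sol) {
      sol$prim <- scale_prim(sol$prim, s)
      sol
    })
    reg
  })
  names(at) <- names(atlas)
  list(landmarks = lm_proj, atlas = at)
}
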