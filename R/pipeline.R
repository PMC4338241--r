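#' Study configuration
#'
#' Configures the full in-silico study: a cohort of synthetic patients,
#' each superimposed with each technique by each simulated operator in each
#' session. Defaults mirror the emulated study design: 8 patients, all
#' five techniques, 3 operators, 2 sessions one month apart.
#'
#' @param n_patients Number of synthetic patients (default 8).
#' @param techniques Subset of `c("3P", "1Z", "BZ", "AC", "ACF")`.
#' @param n_operators Simulated operators (default 3).
#' @param n_sessions Repeated sessions per operator (default 2).
#' @param phantom Named list of [phantom_spec()] argument overrides
#'   (`seed` is derived from `master_seed` per patient).
#' @param icp Named list of [icp_params()] overrides; the study default
#'   uses 4000 sample points per registration.
#' @param operator_sd_mm Landmark-picking jitter SD (default 0.6 mm, calibrated so the three-point duplicate-control deviation falls in the clinically reported range).
#' @param threshold_hu Isosurface threshold in HU (default 500, the usual bone-window setting).
#' @param max_faces Polygon budget per mesh (default 100000).
#' @param patch_area_mm2 Fiducial patch area (default 5).
#' @param master_seed Integer seed fixing the entire study.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_patients = 8,
                         techniques = c("3P", "1Z", "BZ", "AC", "ACF"),
                         n_operators = 3, n_sessions = 2,
                         phantom = list(), icp = list(),
                         operator_sd_mm = 0.6,
                         threshold_hu = 500,
                         max_faces = 100000,
                         patch_area_mm2 = 5,
                         master_seed = 20260101L) {
  stopifnot(n_patients >= 1, n_operators >= 1, n_sessions >= 1,
            all(techniques %in% c("3P", "1Z", "BZ", "AC", "ACF")))
  icp_defaults <- list(sample_count = 4000)
  icp <- utils::modifyList(icp_defaults, icp)
  structure(list(n_patients = n_patients, techniques = techniques,
                 n_operators = n_operators, n_sessions = n_sessions,
                 phantom = phantom, icp = icp,
                 operator_sd_mm = operator_sd_mm,
                 threshold_hu = threshold_hu, max_faces = max_faces,
                 patch_area_mm2 = patch_area_mm2,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

# fiducial patch centres and precision points (landmark names)
.FIDUCIAL_PATCHES <- c("SellaPatchCenter", "ForamenPatchCenterR", "ForamenPatchCenterL")
.PRECISION_POINTS <- c("PiriformL", "PiriformR", "IncisorL", "IncisorR")

# prepare one patient: volumes -> cleaned, budgeted meshes
prepare_patient <- function(config, patient_seed, duplicate_control = FALSE) {
  args <- utils::modifyList(config$phantom, list(seed = patient_seed))
  spec <- do.call(phantom_spec, args)
  surf <- function(vol) {
    m <- extract_isosurface(vol, config$threshold_hu)
    m <- clean_components(m)
    decimate_to_budget(m, config$max_faces)
  }
  if (duplicate_control) {
    ph <- build_phantom(spec)
    mesh_t0 <- surf(ph$volume)
    set.seed(child_seed(patient_seed, 11))
    ctr <- colMeans(mesh_t0$vertices)
    tf <- random_rigid_transform(spec$rescan_rotation_max_deg,
                                 spec$rescan_translation_max_mm, center = ctr)
    truth <- ph$truth
    truth$rescan_transform <- tf
    truth$landmarks_t1 <- transform_points(tf, truth$landmarks_t0)
    list(spec = spec, truth = truth, atlas = ph$atlas,
         mesh_t0 = mesh_t0, mesh_t1 = transform_mesh(mesh_t0, tf))
  } else {
    pat <- make_patient(spec)
    list(spec = spec, truth = pat$truth, atlas = pat$atlas,
         mesh_t0 = surf(pat$volume_t0), mesh_t1 = surf(pat$volume_t1))
  }
}

# run all techniques for one operator/session cell on a prepared patient.
# cell_seed drives the operator's picks (differs per session); icp_seed
# drives ICP surface sampling (per operator only, so that sessions differ
# only through operator behaviour)
run_cell <- function(pp, config, cell_seed, jitter_sd, icp_seed = cell_seed) {
  truth <- pp$truth
  atlas_t1 <- atlas_in_t1(pp$atlas, truth)
  pick0 <- jitter_operator(truth$landmarks_t0, pp$atlas, jitter_sd,
                           pp$mesh_t0, seed = child_seed(cell_seed, 1))
  pick1 <- jitter_operator(truth$landmarks_t1, atlas_t1, jitter_sd,
                           pp$mesh_t1, seed = child_seed(cell_seed, 2))
  t0_bundle <- list(mesh = pp$mesh_t0, landmarks = pick0$landmarks,
                    atlas = pick0$atlas)
  t1_bundle <- list(mesh = pp$mesh_t1, landmarks = pick1$landmarks,
                    atlas = pick1$atlas)

  tree_t0 <- mesh_tree(pp$mesh_t0)
  tree_t1 <- mesh_tree(pp$mesh_t1)

  acc_rows <- list()
  prec_rows <- list()
  errors <- character(0)
  for (tech in config$techniques) {
    res <- tryCatch({
      ip <- do.call(icp_params,
                    utils::modifyList(config$icp,
                                      list(seed = child_seed(icp_seed, match(tech, c("3P", "1Z", "BZ", "AC", "ACF"))))))
      sup <- superimpose(tech, t0_bundle, t1_bundle, params = ip)
      tr <- sup$transform

      # fiducial patches: grown on the T1 mesh around the back-transformed
      # patch centres (face sets are invariant under the rigid motion)
      inv_tr <- invert_transform(tr)
      patches <- lapply(.FIDUCIAL_PATCHES, function(nm) {
        circular_patch(pp$mesh_t1,
                       transform_points(inv_tr, truth$landmarks_t0[nm, ]),
                       config$patch_area_mm2, label = nm, max_dist = 10,
                       tree = tree_t1)
      })
      result_mesh <- transform_mesh(pp$mesh_t1, tr)
      acc <- accuracy_D(result_mesh, pp$mesh_t0, patches,
                        reference_tree = tree_t0)

      prec <- dplyr::bind_rows(lapply(.PRECISION_POINTS, function(nm) {
        landmark_displacement(pick0$landmarks[nm, ], pick1$landmarks[nm, ],
                              tr, label = nm)
      }))
      list(acc = acc, prec = prec, transform = tr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", tech, conditionMessage(res)))
      next
    }
    acc_rows[[tech]] <- tibble::tibble(
      technique = tech, D = res$acc$D_accuracy,
      Dx = mean(res$acc$patch_deviations$Dx),
      Dy = mean(res$acc$patch_deviations$Dy),
      Dz = mean(res$acc$patch_deviations$Dz))
    prec_rows[[tech]] <- dplyr::mutate(res$prec, technique = tech,
                                       .before = 1)
  }
  list(accuracy = dplyr::bind_rows(acc_rows),
       precision = dplyr::bind_rows(prec_rows),
       errors = errors)
}

#' Run the full superimposition study
#'
#' For every synthetic patient: build the T0 phantom, apply the treatment,
#' simulate the rescan, extract meshes; then for every technique x operator
#' x session: superimpose, measure accuracy (patch deviation at the three
#' fiducial areas) and precision (displacement of the four measurement
#' points). Fully reproducible from the master seed.
#'
#' @param config A [study_config()].
#' @param progress Print per-patient progress lines (default `FALSE`).
#' @return List with `accuracy` and `precision` measurement tibbles
#'   (columns `patient`, `technique`, `operator`, `session`,
#'   `patch_or_point`, `D`, `Dx`, `Dy`, `Dz`), a `truths` list of
#'   per-patient ground truth, and an `errors` character vector of
#'   per-cell failures (the run continues past them).
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  acc_all <- list()
  prec_all <- list()
  errors <- character(0)
  truths <- list()
  for (p in seq_len(config$n_patients)) {
    pseed <- child_seed(config$master_seed, 101 * p)
    pp <- prepare_patient(config, pseed)
    truths[[p]] <- pp$truth
    if (progress) {
      message(sprintf("patient %d/%d: T0 %d faces, T1 %d faces", p,
                      config$n_patients, nrow(pp$mesh_t0$faces),
                      nrow(pp$mesh_t1$faces)))
    }
    for (o in seq_len(config$n_operators)) {
      for (s in seq_len(config$n_sessions)) {
        cseed <- child_seed(pseed, 1000 * o + s)
        cell <- run_cell(pp, config, cseed, config$operator_sd_mm,
                         icp_seed = child_seed(pseed, 1000 * o))
        if (nrow(cell$accuracy)) {
          acc_all[[length(acc_all) + 1]] <- dplyr::mutate(
            cell$accuracy, patient = p, operator = o, session = s,
            patch_or_point = "D_accuracy")
        }
        if (nrow(cell$precision)) {
          prec_all[[length(prec_all) + 1]] <- dplyr::mutate(
            cell$precision, patient = p, operator = o, session = s)
        }
        if (length(cell$errors)) {
          errors <- c(errors, sprintf("patient %d op %d session %d %s",
                                      p, o, s, cell$errors))
        }
      }
    }
  }
  tidy_cols <- function(x) {
    dplyr::select(x, dplyr::all_of(c("patient", "technique", "operator",
                                     "session", "patch_or_point",
                                     "D", "Dx", "Dy", "Dz")))
  }
  list(accuracy = tidy_cols(dplyr::bind_rows(acc_all)),
       precision = tidy_cols(dplyr::bind_rows(prec_all)),
       truths = truths, errors = errors)
}

#' Duplicate-model control arm
#'
#' The registration-only control: the "T1" model is an exact rigidly
#' displaced copy of the T0 mesh (no treatment, no new noise, no new
#' rasterisation), superimposed by one operator with every technique. With
#' the surface-based techniques the duplicate should register essentially
#' perfectly; the three-point technique inherits the operator's
#' landmark-picking jitter. Landmark displacements are measured on the
#' exact (unjittered) landmark copies so they isolate registration error.
#'
#' @param config A [study_config()].
#' @return As [run_study()] (single operator, single session).
#' @export
run_duplicate_control <- function(config = study_config()) {
  acc_all <- list()
  prec_all <- list()
  errors <- character(0)
  for (p in seq_len(config$n_patients)) {
    pseed <- child_seed(config$master_seed, 777 + 101 * p)
    pp <- prepare_patient(config, pseed, duplicate_control = TRUE)
    truth <- pp$truth
    atlas_t1 <- atlas_in_t1(pp$atlas, truth)
    pick0 <- jitter_operator(truth$landmarks_t0, pp$atlas, config$operator_sd_mm,
                             pp$mesh_t0, seed = child_seed(pseed, 21))
    pick1 <- jitter_operator(truth$landmarks_t1, atlas_t1, config$operator_sd_mm,
                             pp$mesh_t1, seed = child_seed(pseed, 22))
    t0_bundle <- list(mesh = pp$mesh_t0, landmarks = pick0$landmarks,
                      atlas = pick0$atlas)
    t1_bundle <- list(mesh = pp$mesh_t1, landmarks = pick1$landmarks,
                      atlas = pick1$atlas)
    tree_t0 <- mesh_tree(pp$mesh_t0)
    tree_t1 <- mesh_tree(pp$mesh_t1)
    for (tech in config$techniques) {
      res <- tryCatch({
        ip <- do.call(icp_params,
                      utils::modifyList(config$icp, list(seed = child_seed(pseed, 30 + match(tech, c("3P", "1Z", "BZ", "AC", "ACF"))))))
        sup <- superimpose(tech, t0_bundle, t1_bundle, params = ip)
        tr <- sup$transform
        inv_tr <- invert_transform(tr)
        patches <- lapply(.FIDUCIAL_PATCHES, function(nm) {
          circular_patch(pp$mesh_t1,
                         transform_points(inv_tr, truth$landmarks_t0[nm, ]),
                         config$patch_area_mm2, label = nm, max_dist = 10,
                         tree = tree_t1)
        })
        result_mesh <- transform_mesh(pp$mesh_t1, tr)
        acc <- accuracy_D(result_mesh, pp$mesh_t0, patches,
                          reference_tree = tree_t0)
        prec <- dplyr::bind_rows(lapply(.PRECISION_POINTS, function(nm) {
          landmark_displacement(truth$landmarks_t0[nm, ],
                                truth$landmarks_t1[nm, ], tr, label = nm)
        }))
        list(acc = acc, prec = prec)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("patient %d %s: %s", p, tech,
                                    conditionMessage(res)))
        next
      }
      acc_all[[length(acc_all) + 1]] <- tibble::tibble(
        patient = p, technique = tech, operator = 1L, session = 1L,
        patch_or_point = "D_accuracy", D = res$acc$D_accuracy,
        Dx = mean(res$acc$patch_deviations$Dx),
        Dy = mean(res$acc$patch_deviations$Dy),
        Dz = mean(res$acc$patch_deviations$Dz))
      prec_all[[length(prec_all) + 1]] <- dplyr::mutate(
        res$prec, patient = p, technique = tech, operator = 1L,
        session = 1L, .before = 1)
    }
  }
  tidy_cols <- function(x) {
    dplyr::select(x, dplyr::all_of(c("patient", "technique", "operator",
                                     "session", "patch_or_point",
                                     "D", "Dx", "Dy", "Dz")))
  }
  list(accuracy = tidy_cols(dplyr::bind_rows(acc_all)),
       precision = tidy_cols(dplyr::bind_rows(prec_all)),
       errors = errors)
}

#' Summarise accuracy per operator and technique
#'
#' Median and quartiles (type-6 quantiles) of the accuracy statistic per
#' operator x technique cell, formatted "median (q1, q3)".
#'
#' @param accuracy Accuracy tibble from [run_study()].
#' @return A tibble with one row per operator and one column per technique.
#' @export
summarize_accuracy <- function(accuracy) {
  tab <- accuracy |>
    dplyr::group_by(.data$operator, .data$technique) |>
    dplyr::summarise(cell = sprintf("%.2f (%.2f, %.2f)",
                                    median(.data$D),
                                    quantile(.data$D, 0.25, type = 6),
                                    quantile(.data$D, 0.75, type = 6)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "technique", values_from = "cell")
  tab
}

#' Write the study report
#'
#' Writes tab-separated tables (MANOVA source tables, per-technique
#' accuracy summaries, pairwise matrices, agreement summaries), STL exports
#' of a superimposed example pair with its deviation field, and
#' Bland-Altman difference plots (PDF). Empty inputs produce explicit
#' "no data" placeholders rather than errors.
#'
#' @param tables List with `accuracy` and `precision` tibbles (as from
#'   [run_study()]).
#' @param stats_results Optional list of fitted objects ([permanova()],
#'   [permdisp()], [bland_altman()]...) written alongside.
#' @param outdir Output directory (created if missing).
#' @param meshes Optional list with `result` and `reference` [mesh()]es to
#'   export with a deviation colour channel.
#' @return Character vector of files written, invisibly.
#' @export
make_report <- function(tables, stats_results = list(), outdir, meshes = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(outdir, name)
    if (is.null(df) || nrow(df) == 0) {
      writeLines("no data", path)
    } else {
      utils::write.table(format(as.data.frame(df), digits = 15), path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    written <<- c(written, path)
  }
  wtsv(tables$accuracy, "accuracy_measurements.tsv")
  wtsv(tables$precision, "precision_measurements.tsv")
  if (!is.null(tables$accuracy) && nrow(tables$accuracy)) {
    wtsv(summarize_accuracy(tables$accuracy), "accuracy_by_operator.tsv")
  } else {
    wtsv(NULL, "accuracy_by_operator.tsv")
  }
  for (nm in names(stats_results)) {
    obj <- stats_results[[nm]]
    if (inherits(obj, "cr_permanova")) {
      wtsv(tidy(obj), paste0(nm, "_permanova.tsv"))
    } else if (inherits(obj, "cr_permdisp")) {
      wtsv(glance(obj), paste0(nm, "_permdisp.tsv"))
    } else if (inherits(obj, "cr_bland_altman")) {
      wtsv(glance(obj), paste0(nm, "_agreement.tsv"))
      path <- file.path(outdir, paste0(nm, "_difference_plot.pdf"))
      grDevices::pdf(path, width = 6, height = 5)
      print(ggplot2::autoplot(obj))
      grDevices::dev.off()
      written <- c(written, path)
    } else if (is.data.frame(obj)) {
      wtsv(obj, paste0(nm, ".tsv"))
    }
  }
  if (!is.null(meshes)) {
    dev <- deviation_field(meshes$result, meshes$reference)
    p1 <- file.path(outdir, "superimposed_result.stl")
    p2 <- file.path(outdir, "reference.stl")
    write_stl(dev, p1)
    write_stl(meshes$reference, p2)
    sc <- file.path(outdir, "superimposed_result_deviation.tsv")
    utils::write.table(data.frame(vertex = seq_along(dev$scalar),
                                  signed_deviation_mm = dev$scalar),
                       sc, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p1, p2, sc)
  }
  manifest <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(list(files = basename(written),
                            written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, manifest)
  invisible(written)
}
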