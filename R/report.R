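#' Default pipeline configuration
#'
#' One place for every tunable the validation pipeline uses, so deviations
#' from the defaults are always explicit. Values of note: landmark region
#' radius 5 mm; femoral valgus (anatomical-to-mechanical) angle 5 degrees;
#' resection offsets 9 mm; tibial posterior slope 3 degrees (a package
#' default - the slope value itself is surgeon- and implant-specific);
#' contour rendering resolution 0.1 mm.
#'
#' @return a named list of parameters.
#' @export
default_config <- function() {
  list(
    landmark_radius_mm = 5,
    region_membership = "euclidean",
    valgus_angle_deg = 5,
    tibial_slope_deg = 3,
    femoral_offset_mm = 9,
    tibial_offset_mm = 9,
    contour_spacing_mm = 0.1,
    shaft_fraction_range = c(0.25, 0.75),
    iso_level = 0.5,
    mask_smooth_sigma = 1,
    icp = list(max_iterations = 100L, tolerance = 1e-6,
               max_correspondence = 10)
  )
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of the [default_config()] structure; unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return for `read_config`, the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(base, user)
}

#' @rdname read_config
#' @param config configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Published per-patient global RMSE reference table
#'
#' The per-patient global surface RMSE values (mm, femur and tibia)
#' published by an 18-patient clinical validation of X-ray-based knee
#' reconstruction against CT ground truth. Shipped as a plain-text table;
#' used to verify that the package's cohort aggregation reproduces the
#' published mean and SD.
#'
#' @return data.frame with columns `patient`, `femur`, `tibia`.
#' @export
reference_global_rmse <- function() {
  path <- system.file("extdata", "reference_global_rmse.csv",
                      package = "kneeval")
  utils::read.csv(path)
}

#' Mean and sample standard deviation of a metric across patients
#'
#' SD uses the n-1 denominator (this is what reproduces the published
#' cohort summary from the published per-patient values). Display rounding
#' is left to [format_mean_sd()]; full precision is retained here.
#'
#' @param values numeric vector of per-patient values.
#' @return list with `mean`, `sd` (NA for a single value) and `n`.
#' @export
cohort_mean_sd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no values to aggregate")
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Format a mean and SD for display
#'
#' @param mean,sd numeric values.
#' @param digits decimals for display (default 2).
#' @return character scalar like `"0.93 +- 0.25"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  sprintf(paste0("%.", digits, "f +- %.", digits, "f"), mean, sd)
}

#' Validate one bone: registration, RMSE, regions, cuts, contours, axes
#'
#' Runs the full single-bone pipeline in study order: ICP registration of
#' the prediction to the ground truth, global RMSE, landmark consensus
#' regions with local RMSE, simulated resection plane (distal femoral or
#' proximal tibial), cut contours on both models with the plane derived
#' from the ground-truth model, contour RMSE, and - for annotated axes -
#' baseline and cross-modality angular statistics. Optional stages with
#' missing inputs are skipped with a warning.
#'
#' @param pred_mesh prediction [triangle_mesh()].
#' @param gt_mesh ground-truth [triangle_mesh()].
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"right"` or `"left"`; left-side inputs are mirrored into the
#'   right-knee convention.
#' @param patient_id identifier.
#' @param annotations optional [landmark_annotations()] for this bone
#'   (both model sources).
#' @param config a [default_config()]-shaped list.
#' @return list with the bone's metrics (class `bone_record`).
#' @export
validate_bone <- function(pred_mesh, gt_mesh, bone, side = "right",
                          patient_id = "patient", annotations = NULL,
                          config = default_config()) {
  stopifnot(is_triangle_mesh(pred_mesh), is_triangle_mesh(gt_mesh))
  if (side == "left") {
    pred_mesh <- mirror_mesh_x(pred_mesh)
    gt_mesh <- mirror_mesh_x(gt_mesh)
    if (!is.null(annotations)) annotations$x <- -annotations$x
  }
  pred <- bone_model(pred_mesh, bone, "right", "prediction", patient_id)
  gt <- bone_model(gt_mesh, bone, "right", "ground_truth", patient_id)

  transform <- icp_register(pred$mesh, gt$mesh,
                            max_iterations = config$icp$max_iterations,
                            tolerance = config$icp$tolerance,
                            max_correspondence = config$icp$max_correspondence)
  reg_mesh <- transform_mesh(pred$mesh, transform)
  reg_pred <- bone_model(reg_mesh, bone, "right", "prediction", patient_id)
  gres <- global_rmse(reg_pred, gt, register = FALSE, keep_distances = FALSE)
  rec <- list(patient_id = patient_id, bone = bone, side = side,
              registration = transform,
              global_rmse = gres$rmse, n_points = gres$n_points)

  ann_reg <- NULL
  if (!is.null(annotations)) {
    ann_reg <- annotations[annotations$bone == bone, , drop = FALSE]
    is_pred <- ann_reg$model_source == "prediction"
    if (any(is_pred)) {
      moved <- apply_rigid(as.matrix(ann_reg[is_pred, c("x", "y", "z")]),
                           transform)
      ann_reg[is_pred, c("x", "y", "z")] <- moved
    }
  }

  # landmark regions on the registered prediction, compared to ground truth
  rec$landmarks <- NULL
  if (!is.null(ann_reg) && any(ann_reg$model_source == "prediction")) {
    rows <- lapply(landmark_names(bone, "region"), function(lm) {
      sub <- ann_reg[ann_reg$landmark == lm &
                       ann_reg$model_source == "prediction", , drop = FALSE]
      if (nrow(sub) < 3L) return(NULL)
      region <- tryCatch(
        build_region(sub, reg_mesh, radius = config$landmark_radius_mm,
                     membership = config$region_membership),
        error = function(e) {
          warning("landmark ", lm, ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(region)) return(NULL)
      lr <- local_rmse(region, gt$mesh)
      data.frame(landmark = lm, n_inliers = length(region$inlier_annotations),
                 n_member_vertices = length(region$member_vertices),
                 radius_mm = region$radius, local_rmse_mm = lr$rmse)
    })
    rec$landmarks <- do.call(rbind, rows)
  } else if (!is.null(annotations)) {
    warning("no prediction-side annotations for ", bone,
            "; landmark stage skipped", call. = FALSE)
  }

  # resection plane from the ground-truth model, contours from both models
  plane <- tryCatch({
    anat <- fit_anatomical_axis(gt$mesh, config$shaft_fraction_range)
    if (bone == "femur") {
      mech <- estimate_mechanical_axis(anat, config$valgus_angle_deg, "right")
      femoral_cut_plane(mech, gt$mesh, config$femoral_offset_mm, "right")
    } else {
      tibial_cut_plane(anat, gt$mesh, config$tibial_slope_deg,
                       config$tibial_offset_mm)
    }
  }, error = function(e) {
    warning("cut-plane stage skipped: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  if (!is.null(plane)) {
    rec$cut_plane <- plane
    contour_res <- tryCatch({
      gt_loops <- extract_cut_contour(gt$mesh, plane,
                                      config$contour_spacing_mm)
      pred_loops <- extract_cut_contour(reg_mesh, plane,
                                        config$contour_spacing_mm)
      contour_rmse(pred_loops[[1L]], gt_loops[[1L]])
    }, error = function(e) {
      warning("contour stage skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(contour_res)) rec$contour_rmse <- contour_res$rmse

    if (!is.null(ann_reg)) {
      axis_names <- if (bone == "femur") c("TEA", "PCA") else "MLTA"
      rec$axis_stats <- list()
      for (ax in axis_names) {
        ct <- build_annotated_axes(ann_reg, ax, "ground_truth")
        xr <- build_annotated_axes(ann_reg, ax, "prediction")
        if (length(ct) < 2L || length(xr) < 1L) {
          warning("axis ", ax, ": insufficient annotations", call. = FALSE)
          next
        }
        ct2 <- lapply(ct, project_axis, plane = plane)
        xr2 <- lapply(xr, project_axis, plane = plane)
        rec$axis_stats[[ax]] <- list(baseline = baseline_stats(ct2),
                                     cross = cross_stats(ct2, xr2))
      }
    }
  }
  class(rec) <- "bone_record"
  rec
}

#' Run the validation pipeline for one patient
#'
#' Consumes a patient directory in the cohort layout
#' (`{femur,tibia}_{gt,pred}.stl`, optional `{bone}_gt.nii.gz` used when
#' the STL ground truth is absent, optional `annotations.json`) and returns
#' a patient record with per-bone metrics. Missing optional inputs produce
#' warnings, not failures; a missing required mesh is an error.
#'
#' @param patient_dir path to the patient directory.
#' @param config a [default_config()]-shaped list.
#' @param side bone laterality; read from the annotations when present
#'   (default `"right"`).
#' @return list of class `patient_record` with elements `patient_id` and
#'   one `bone_record` per available bone.
#' @export
run_patient <- function(patient_dir, config = default_config(),
                        side = "right") {
  stopifnot(dir.exists(patient_dir))
  patient_id <- basename(patient_dir)
  ann_path <- file.path(patient_dir, "annotations.json")
  annotations <- if (file.exists(ann_path)) read_annotations_json(ann_path)
  if (!is.null(annotations) && nrow(annotations) > 0L)
    side <- annotations$side[1L]

  record <- list(patient_id = patient_id, side = side)
  for (bone in c("femur", "tibia")) {
    pred_path <- file.path(patient_dir, paste0(bone, "_pred.stl"))
    gt_stl <- file.path(patient_dir, paste0(bone, "_gt.stl"))
    gt_nii <- file.path(patient_dir, paste0(bone, "_gt.nii.gz"))
    if (!file.exists(pred_path)) {
      warning("missing prediction mesh for ", bone, " of ", patient_id,
              call. = FALSE)
      next
    }
    gt_mesh <- if (file.exists(gt_stl)) {
      read_stl(gt_stl)
    } else if (file.exists(gt_nii)) {
      mask_to_mesh(load_mask(gt_nii), iso_level = config$iso_level,
                   smooth_sigma = config$mask_smooth_sigma)
    } else {
      stop("missing ground truth (STL or NIfTI) for ", bone, " of ",
           patient_id)
    }
    record[[bone]] <- validate_bone(read_stl(pred_path), gt_mesh, bone,
                                    side = side, patient_id = patient_id,
                                    annotations = annotations,
                                    config = config)
  }
  class(record) <- "patient_record"
  record
}

#' Aggregate patient records into a cohort summary
#'
#' Mean and sample SD (n-1) of every metric across patients: global RMSE
#' and contour RMSE per bone, local RMSE per landmark. Display rounding
#' never feeds back into the stored full-precision values.
#'
#' @param records list of `patient_record` objects.
#' @return data.frame of class `cohort_summary` with columns `metric`,
#'   `mean`, `sd`, `n`, `display`.
#' @export
aggregate_records <- function(records) {
  if (length(records) == 0L) stop("no patient records to aggregate")
  pull <- function(fn) vapply(records, fn, numeric(1))
  metrics <- list()
  for (bone in c("femur", "tibia")) {
    metrics[[paste0("global_rmse_", bone)]] <-
      pull(function(r) r[[bone]]$global_rmse %||% NA_real_)
    metrics[[paste0("contour_rmse_", bone)]] <-
      pull(function(r) r[[bone]]$contour_rmse %||% NA_real_)
  }
  lm_names <- landmark_names("all", "region")
  for (lm in lm_names) {
    metrics[[paste0("local_rmse_", lm)]] <- pull(function(r) {
      bone <- landmark_table()$bone[match(lm, landmark_table()$landmark)]
      tab <- r[[bone]]$landmarks
      if (is.null(tab)) return(NA_real_)
      val <- tab$local_rmse_mm[tab$landmark == lm]
      if (length(val) == 1L) val else NA_real_
    })
  }
  rows <- lapply(names(metrics), function(m) {
    vals <- metrics[[m]]
    if (all(!is.finite(vals))) return(NULL)
    s <- cohort_mean_sd(vals)
    data.frame(metric = m, mean = s$mean, sd = s$sd, n = s$n,
               display = format_mean_sd(s$mean, s$sd))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write cohort report CSVs
#'
#' Emits `global_rmse.csv` (one row per patient, femur and tibia columns,
#' plus a mean/SD summary row), `landmark_rmse.csv` (long form),
#' `contour_rmse.csv`, and `axis_angles.csv` (one row per axis with
#' baseline and cross-modality mean/SD pooled across bones).
#'
#' @param records list of `patient_record` objects.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_reports <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- data.frame(
    patient = vapply(records, function(r) r$patient_id, character(1)),
    femur = vapply(records, function(r) r$femur$global_rmse %||% NA_real_,
                   numeric(1)),
    tibia = vapply(records, function(r) r$tibia$global_rmse %||% NA_real_,
                   numeric(1)))
  fm <- cohort_mean_sd(gr$femur)
  tb <- cohort_mean_sd(gr$tibia)
  gr_out <- rbind(
    data.frame(patient = gr$patient, femur = sprintf("%.2f", gr$femur),
               tibia = sprintf("%.2f", gr$tibia)),
    data.frame(patient = "Mean +- SD",
               femur = format_mean_sd(fm$mean, fm$sd),
               tibia = format_mean_sd(tb$mean, tb$sd)))
  utils::write.csv(gr_out, file.path(dir, "global_rmse.csv"),
                   row.names = FALSE)

  lm_rows <- do.call(rbind, lapply(records, function(r) {
    do.call(rbind, lapply(c("femur", "tibia"), function(bone) {
      tab <- r[[bone]]$landmarks
      if (is.null(tab)) return(NULL)
      cbind(patient = r$patient_id, bone = bone, tab)
    }))
  }))
  if (!is.null(lm_rows))
    utils::write.csv(lm_rows, file.path(dir, "landmark_rmse.csv"),
                     row.names = FALSE)

  ct <- data.frame(
    patient = gr$patient,
    femur = vapply(records, function(r) r$femur$contour_rmse %||% NA_real_,
                   numeric(1)),
    tibia = vapply(records, function(r) r$tibia$contour_rmse %||% NA_real_,
                   numeric(1)))
  utils::write.csv(ct, file.path(dir, "contour_rmse.csv"), row.names = FALSE)

  stats_list <- list()
  for (r in records) for (bone in c("femur", "tibia")) {
    for (s in r[[bone]]$axis_stats) {
      stats_list <- c(stats_list, list(s$baseline, s$cross))
    }
  }
  if (length(stats_list) > 0L)
    utils::write.csv(study_axis_report(stats_list),
                     file.path(dir, "axis_angles.csv"), row.names = FALSE)
  invisible(dir)
}
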