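#' Specification of a stylized synthetic bone
#'
#' The generator builds deliberately stylized femur- and tibia-like closed
#' meshes as unions of analytic primitives (capsule shaft, ellipsoidal
#' condyles/plateau lobes, spherical tuberosity, a flattened anterior
#' cortex facet) sampled on an implicit field and isosurfaced. Stylization
#' is a feature: every landmark has an exact analytic coordinate, so the
#' whole validation pipeline can be tested against known truth.
#'
#' Coordinates follow the package's right-knee patient frame: +x
#' left-to-right (lateral for a right knee), +y posterior-to-anterior, +z
#' distal-to-proximal, all in mm. The knee joint line sits near z = 0; the
#' femur occupies z > 0 and the tibia z < 0.
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"right"` (default) or `"left"` (mirrored in x).
#' @param shaft_length shaft extent in mm (default 150 femur, 130 tibia).
#' @param shaft_radius shaft radius in mm (default 14 femur, 12 tibia).
#' @param condyle_radii length-3 semi-axes (mm) of the condylar or plateau
#'   ellipsoids.
#' @param mesh_density target edge length in mm = isosurface grid spacing
#'   (default 1); must not exceed `shaft_radius / 5`.
#' @param size_jitter relative SD of the seeded random scaling applied to
#'   the primitive dimensions, emulating anatomic variation (default 0.03).
#' @param seed integer seed controlling the size jitter.
#' @return an object of class `synthetic_bone_spec`.
#' @export
synthetic_bone_spec <- function(bone = c("femur", "tibia"),
                                side = c("right", "left"),
                                shaft_length = NULL, shaft_radius = NULL,
                                condyle_radii = NULL, mesh_density = 1,
                                size_jitter = 0.03, seed = 1L) {
  bone <- match.arg(bone)
  side <- match.arg(side)
  if (is.null(shaft_length)) shaft_length <- if (bone == "femur") 150 else 130
  if (is.null(shaft_radius)) shaft_radius <- if (bone == "femur") 14 else 12
  if (is.null(condyle_radii))
    condyle_radii <- if (bone == "femur") c(14, 17, 15) else c(15, 19, 10)
  stopifnot(shaft_length > 0, shaft_radius > 0, all(condyle_radii > 0),
            mesh_density > 0, size_jitter >= 0)
  if (mesh_density > shaft_radius / 5)
    stop("mesh_density too coarse: must be <= shaft_radius / 5 for adequate sampling")
  structure(list(bone = bone, side = side, shaft_length = shaft_length,
                 shaft_radius = shaft_radius, condyle_radii = condyle_radii,
                 mesh_density = mesh_density, size_jitter = size_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_bone_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# signed distance to a capsule (segment a-b with radius r)
capsule_sdf <- function(px, py, pz, a, b, r) {
  abv <- b - a
  len2 <- sum(abv^2)
  t <- ((px - a[1]) * abv[1] + (py - a[2]) * abv[2] + (pz - a[3]) * abv[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - a[1] - t * abv[1])^2 + (py - a[2] - t * abv[2])^2 +
         (pz - a[3] - t * abv[3])^2) - r
}

# quadratic ellipsoid field: negative inside, zero on the surface
ellipsoid_field <- function(px, py, pz, center, radii) {
  ((px - center[1]) / radii[1])^2 + ((py - center[2]) / radii[2])^2 +
    ((pz - center[3]) / radii[3])^2 - 1
}

sphere_sdf <- function(px, py, pz, center, r) {
  sqrt((px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2) - r
}

# analytic implicit model of one bone: field function + landmark truth map
bone_implicit_model <- function(spec) {
  scale <- if (spec$size_jitter > 0) {
    with_seed(spec$seed, exp(stats::rnorm(4L, sd = spec$size_jitter)))
  } else rep(1, 4L)
  L <- spec$shaft_length * scale[1L]
  R <- spec$shaft_radius * scale[2L]
  cr <- spec$condyle_radii * scale[3L]

  if (spec$bone == "femur") {
    cx <- (18 + cr[1L] - 14) * scale[4L]      # condyle centre offset
    ccen <- list(lateral = c(cx, -4, cr[3L] + 1),
                 medial = c(-cx, -4, cr[3L] + 1))
    shaft_a <- c(0, 4, 2 * cr[3L])
    shaft_b <- c(0, 4, L)
    flat_y <- 4 + R - 2                        # anterior cortex facet plane
    flat_z <- 2 * cr[3L] + 14
    field <- function(px, py, pz) {
      f <- pmin(capsule_sdf(px, py, pz, shaft_a, shaft_b, R),
                ellipsoid_field(px, py, pz, ccen$lateral, cr),
                ellipsoid_field(px, py, pz, ccen$medial, cr))
      carve <- (py - flat_y) - 6 * ((pz - flat_z) / 10)^2 - 6 * (px / 12)^2
      pmax(f, carve)
    }
    lm <- rbind(
      posterior_lateral_condyle = ccen$lateral + c(0, -cr[2L], 0),
      posterior_medial_condyle  = ccen$medial + c(0, -cr[2L], 0),
      lateral_distal_condyle    = ccen$lateral + c(0, 0, -cr[3L]),
      medial_distal_condyle     = ccen$medial + c(0, 0, -cr[3L]),
      anterior_cortex           = c(0, flat_y, flat_z),
      lateral_epicondyle        = ccen$lateral + c(cr[1L], 0, 0),
      medial_epicondyle         = ccen$medial + c(-cr[1L], 0, 0))
    bbox <- rbind(c(-(cx + cr[1L]), -4 - cr[2L], 0),
                  c(cx + cr[1L], 4 + R, L + R))
  } else {
    px_off <- (14 + cr[1L] - 15) * scale[4L]  # plateau lobe centre offset
    pcen <- list(lateral = c(px_off, -2, -cr[3L] + 1),
                 medial = c(-px_off, -2, -cr[3L] + 1))
    shaft_a <- c(0, 0, -L)
    shaft_b <- c(0, 0, -2 * cr[3L])
    tub_c <- c(0, R, -3 * cr[3L])
    tub_r <- 7 * scale[4L]
    field <- function(px, py, pz) {
      pmin(capsule_sdf(px, py, pz, shaft_a, shaft_b, R),
           ellipsoid_field(px, py, pz, pcen$lateral, cr),
           ellipsoid_field(px, py, pz, pcen$medial, cr),
           sphere_sdf(px, py, pz, tub_c, tub_r))
    }
    lm <- rbind(
      lateral_plateau = pcen$lateral + c(0, 0, cr[3L]),
      medial_plateau  = pcen$medial + c(0, 0, cr[3L]),
      tuberosity      = tub_c + c(0, tub_r, 0))
    bbox <- rbind(c(-(px_off + cr[1L]), -2 - cr[2L], -L - R),
                  c(px_off + cr[1L], R + tub_r, 1.5))
  }
  list(field = field, landmarks = lm, bbox = bbox)
}

#' Generate a synthetic bone model with exact landmark truth
#'
#' Samples the bone's implicit field on a regular grid at the requested
#' mesh density and extracts the zero isosurface, yielding a closed,
#' watertight triangle mesh together with the exact analytic coordinates of
#' every landmark (the eight region landmarks plus the femoral epicondyle
#' axis endpoints). Deterministic for a fixed spec and seed.
#'
#' @param spec a [synthetic_bone_spec()].
#' @param patient_id patient identifier for the resulting model.
#' @return list with elements `model` (a ground-truth [bone_model()] kept
#'   in the generated frame), `landmarks` (matrix, one named row per
#'   landmark) and `spec`.
#' @export
generate_bone <- function(spec, patient_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_bone_spec"))
  im <- bone_implicit_model(spec)
  h <- spec$mesh_density
  margin <- 3 * h
  origin <- im$bbox[1L, ] - margin
  upper <- im$bbox[2L, ] + margin
  dims <- as.integer(ceiling((upper - origin) / h)) + 1L
  gx <- origin[1L] + (seq_len(dims[1L]) - 1L) * h
  gy <- origin[2L] + (seq_len(dims[2L]) - 1L) * h
  gz <- origin[3L] + (seq_len(dims[3L]) - 1L) * h
  px <- rep(gx, times = dims[2L] * dims[3L])
  py <- rep(rep(gy, each = dims[1L]), times = dims[3L])
  pz <- rep(gz, each = dims[1L] * dims[2L])
  field <- array(im$field(px, py, pz), dim = dims)
  mesh <- isosurface_from_field(field, 0, spacing = rep(h, 3L),
                                origin = origin)
  landmarks <- im$landmarks
  if (spec$side == "left") {
    mesh <- mirror_mesh_x(mesh)
    landmarks[, 1L] <- -landmarks[, 1L]
  }
  model <- bone_model(mesh, bone = spec$bone, side = spec$side,
                      source = "ground_truth", patient_id = patient_id,
                      mirror_left = FALSE)
  list(model = model, landmarks = landmarks, spec = spec)
}

#' Perturbation emulating an X-ray reconstruction of a bone
#'
#' @param rigid initial rigid misalignment, a [rigid_transform()].
#' @param offset_rms RMS amplitude of the smooth surface offset field (mm).
#' @param offset_correlation_length spatial correlation length of the
#'   offset field (mm, default 20); must be at least twice the mesh edge
#'   length.
#' @param seed integer seed for the offset field.
#' @return an object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(rigid = rigid_transform(), offset_rms = 0.9,
                              offset_correlation_length = 20, seed = 1L) {
  stopifnot(inherits(rigid, "rigid_transform"), offset_rms >= 0,
            offset_correlation_length > 0)
  structure(list(rigid = rigid, offset_rms = offset_rms,
                 offset_correlation_length = offset_correlation_length,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

median_edge_length <- function(mesh) {
  f <- mesh$faces
  take <- seq_len(min(nrow(f), 2000L))
  e <- sqrt(rowSums((mesh$vertices[f[take, 1L], , drop = FALSE] -
                       mesh$vertices[f[take, 2L], , drop = FALSE])^2))
  stats::median(e)
}

#' Perturb a ground-truth bone into a synthetic "reconstruction"
#'
#' Applies a smooth random offset field along the outward vertex normals -
#' a truncated Gaussian radial-basis expansion with the requested
#' correlation length, rescaled so the realized RMS equals `offset_rms`
#' exactly - followed by the rigid misalignment. The mesh topology is
#' preserved, so the per-vertex truth of the injected error is known.
#'
#' @param gt a ground-truth [bone_model()].
#' @param p a [perturbation_spec()].
#' @return a prediction [bone_model()] with attributes `true_offset`
#'   (per-vertex signed offsets, mm) and `perturbation` (the spec).
#' @export
perturb_bone <- function(gt, p) {
  stopifnot(inherits(gt, "bone_model"), inherits(p, "perturbation_spec"))
  if (gt$source != "ground_truth")
    stop("perturb_bone expects a ground-truth model")
  mesh <- gt$mesh
  edge <- median_edge_length(mesh)
  if (p$offset_correlation_length < 2 * edge)
    stop("offset_correlation_length must be at least twice the mesh edge length")
  v <- mesh$vertices
  offsets <- numeric(nrow(v))
  if (p$offset_rms > 0) {
    ell <- p$offset_correlation_length
    n_centers <- max(50L, min(500L, ceiling(mesh_area(mesh) / ell^2)))
    offsets <- with_seed(p$seed, {
      centers <- v[sample.int(nrow(v), n_centers), , drop = FALSE]
      amp <- stats::rnorm(n_centers)
      d2 <- outer(rowSums(v^2), rep(1, n_centers)) +
        outer(rep(1, nrow(v)), rowSums(centers^2)) -
        2 * v %*% t(centers)
      as.numeric(exp(-pmax(d2, 0) / (2 * ell^2)) %*% amp)
    })
    rms <- sqrt(mean(offsets^2))
    if (rms == 0) stop("degenerate offset field")
    offsets <- offsets * p$offset_rms / rms
  }
  normals <- vertex_normals(mesh)
  pert <- triangle_mesh(v + offsets * normals, mesh$faces)
  pert <- transform_mesh(pert, p$rigid)
  out <- bone_model(pert, bone = gt$bone, side = gt$side,
                    source = "prediction", patient_id = gt$patient_id,
                    mirror_left = FALSE)
  attr(out, "true_offset") <- offsets
  attr(out, "perturbation") <- p
  out
}

#' Observer annotation noise model
#'
#' Per-observer systematic bias (one 3D vector per observer, SD
#' `observer_bias_sd` per component) plus independent per-repeat noise (SD
#' `repeat_sd` per component). Defaults emulate the study design of three
#' observers annotating each model twice, with magnitudes in the range
#' reported for landmark annotation on knee CT (intra-observer about 1 mm,
#' inter-observer up to a few mm).
#'
#' @param n_observers number of observers (default 3).
#' @param n_repeats annotation repeats per observer (default 2).
#' @param observer_bias_sd per-component SD of observer bias, mm
#'   (default 1.5).
#' @param repeat_sd per-component SD of repeat noise, mm (default 1).
#' @param seed integer seed.
#' @return an object of class `annotation_noise_spec`.
#' @export
annotation_noise_spec <- function(n_observers = 3L, n_repeats = 2L,
                                  observer_bias_sd = 1.5, repeat_sd = 1,
                                  seed = 1L) {
  stopifnot(n_observers >= 1L, n_repeats >= 1L, observer_bias_sd >= 0,
            repeat_sd >= 0)
  structure(list(n_observers = as.integer(n_observers),
                 n_repeats = as.integer(n_repeats),
                 observer_bias_sd = observer_bias_sd, repeat_sd = repeat_sd,
                 seed = as.integer(seed)),
            class = "annotation_noise_spec")
}

#' Simulate observer landmark annotations on a model
#'
#' Each observer receives a fixed random bias; every (landmark, repeat)
#' annotation adds independent repeat noise and is snapped to the nearest
#' mesh vertex, yielding exactly `n_observers x n_repeats` annotations per
#' landmark.
#'
#' @param landmarks landmark truth matrix (named rows) as returned by
#'   [generate_bone()].
#' @param mesh the [triangle_mesh()] the annotations are placed on.
#' @param noise an [annotation_noise_spec()].
#' @param model_source `"prediction"` or `"ground_truth"`.
#' @param patient_id,bone,side metadata copied onto every row.
#' @return a [landmark_annotations()] table.
#' @export
simulate_annotations <- function(landmarks, mesh, noise, model_source,
                                 patient_id = "synthetic", bone = "femur",
                                 side = "right") {
  stopifnot(inherits(noise, "annotation_noise_spec"), is_triangle_mesh(mesh))
  nl <- nrow(landmarks)
  rows <- with_seed(noise$seed, {
    bias <- matrix(stats::rnorm(3L * noise$n_observers,
                                sd = noise$observer_bias_sd),
                   noise$n_observers, 3L)
    grid <- expand.grid(landmark = rownames(landmarks),
                        observer = seq_len(noise$n_observers),
                        rep = seq_len(noise$n_repeats),
                        stringsAsFactors = FALSE)
    pts <- landmarks[grid$landmark, , drop = FALSE] +
      bias[grid$observer, , drop = FALSE] +
      matrix(stats::rnorm(3L * nrow(grid), sd = noise$repeat_sd),
             nrow(grid), 3L)
    snapped <- mesh$vertices[nearest_indices(pts, mesh$vertices), ,
                             drop = FALSE]
    data.frame(patient_id = patient_id, bone = bone, side = side,
               model_source = model_source, landmark = grid$landmark,
               observer_id = sprintf("obs%02d", grid$observer),
               repeat_index = grid$rep,
               x = snapped[, 1L], y = snapped[, 2L], z = snapped[, 3L])
  })
  landmark_annotations(rows)
}

#' Generate a synthetic validation cohort on disk
#'
#' Writes, per patient, ground-truth and perturbed ("reconstructed") femur
#' and tibia STL meshes, a voxelized ground-truth NIfTI mask, an
#' annotation JSON for both models of each bone, and a manifest recording
#' every true parameter (per-stage child seeds, rigid misalignments, offset
#' RMS values) for parameter-recovery tests.
#'
#' Per-patient offset-field RMS values are drawn from the cohort
#' distributions `femur_rms` and `tibia_rms` (mean, SD), truncated at
#' 0.3 mm.
#'
#' @param dir output directory.
#' @param n_patients number of patients (default 18).
#' @param seed master seed; all child seeds derive from it.
#' @param mesh_density generator grid spacing, mm (default 1).
#' @param femur_rms,tibia_rms length-2 (mean, SD) of the per-patient
#'   offset RMS in mm.
#' @param noise an [annotation_noise_spec()] template (its seed is
#'   re-derived per patient).
#' @param voxel_spacing NIfTI mask voxel size, mm (default 1).
#' @param write_masks write ground-truth NIfTI masks (default `TRUE`).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
make_cohort <- function(dir, n_patients = 18L, seed = 1L, mesh_density = 1,
                        femur_rms = c(0.93, 0.25), tibia_rms = c(0.88, 0.14),
                        noise = annotation_noise_spec(),
                        voxel_spacing = 1, write_masks = TRUE,
                        overwrite = FALSE) {
  stopifnot(n_patients >= 1L)
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty (use overwrite = TRUE): ",
         dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  child_seed <- function(i, stage)  # stays below 2^31 - 1
    as.integer((as.numeric(seed) * 7919 + i * 1009 + stage * 101) %%
                 2147483562)
  sides <- with_seed(child_seed(0L, 0L),
                     sample(c("right", "left"), n_patients, replace = TRUE,
                            prob = c(11, 7) / 18))
  manifest <- list(master_seed = as.integer(seed), n_patients = n_patients,
                   mesh_density = mesh_density, patients = list())

  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%03d", i)
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    pat <- list(patient_id = pid, side = sides[i], bones = list())
    for (bone in c("femur", "tibia")) {
      stage <- if (bone == "femur") 1L else 2L
      rms_par <- if (bone == "femur") femur_rms else tibia_rms
      spec <- synthetic_bone_spec(bone = bone, side = sides[i],
                                  mesh_density = mesh_density,
                                  seed = child_seed(i, stage))
      gen <- generate_bone(spec, patient_id = pid)
      draw <- with_seed(child_seed(i, stage + 10L), {
        list(rms = max(0.3, stats::rnorm(1L, rms_par[1L], rms_par[2L])),
             rot_axis = stats::rnorm(3L),
             rot_angle = stats::rnorm(1L, sd = 1),
             trans = stats::rnorm(3L, sd = 1))
      })
      rigid <- rigid_transform(rotation_about_axis(draw$rot_axis,
                                                   draw$rot_angle),
                               draw$trans)
      pert <- perturbation_spec(rigid = rigid, offset_rms = draw$rms,
                                seed = child_seed(i, stage + 20L))
      pred <- perturb_bone(gen$model, pert)
      write_stl(gen$model$mesh, file.path(pdir, paste0(bone, "_gt.stl")))
      write_stl(pred$mesh, file.path(pdir, paste0(bone, "_pred.stl")))
      if (write_masks) {
        mask <- voxelize_mesh(gen$model$mesh, spacing = voxel_spacing)
        write_mask_nifti(mask, file.path(pdir, paste0(bone, "_gt.nii.gz")))
      }
      ann_gt <- simulate_annotations(
        gen$landmarks, gen$model$mesh,
        annotation_noise_spec(noise$n_observers, noise$n_repeats,
                              noise$observer_bias_sd, noise$repeat_sd,
                              seed = child_seed(i, stage + 30L)),
        "ground_truth", pid, bone, sides[i])
      ann_pred <- simulate_annotations(
        gen$landmarks, pred$mesh,
        annotation_noise_spec(noise$n_observers, noise$n_repeats,
                              noise$observer_bias_sd, noise$repeat_sd,
                              seed = child_seed(i, stage + 40L)),
        "prediction", pid, bone, sides[i])
      pat$bones[[bone]] <- list(
        spec_seed = spec$seed, offset_rms = draw$rms,
        offset_seed = pert$seed,
        rigid_rotation_deg = rotation_angle_deg(rigid$rotation),
        rigid_translation = rigid$translation,
        annotation_seeds = c(child_seed(i, stage + 30L),
                             child_seed(i, stage + 40L)))
      pat$annotations[[bone]] <- rbind(ann_gt, ann_pred)
    }
    ann_all <- do.call(rbind, pat$annotations)
    write_annotations_json(landmark_annotations(ann_all),
                           file.path(pdir, "annotations.json"))
    pat$annotations <- NULL
    manifest$patients[[pid]] <- pat
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
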