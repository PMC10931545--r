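test_that("generated bones are closed meshes with on-surface landmarks", {
  for (bone in c("femur", "tibia")) {
    spec <- synthetic_bone_spec(bone, mesh_density = 2, seed = 17)
    gen <- generate_bone(spec)
    mesh <- gen$model$mesh
    expect_gt(mesh_volume(mesh), 0)
    # watertight: every edge shared by exactly two faces
    f <- mesh$faces
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    expect_true(all(table(key) == 2L))
    d <- point_to_mesh_distance(gen$landmarks, mesh)
    expect_true(all(d < spec$mesh_density))
    expected_lm <- if (bone == "femur") 7L else 3L  # regions + axis endpoints
    expect_equal(nrow(gen$landmarks), expected_lm)
  }
})

test_that("generation is deterministic and left sides mirror in x", {
  spec <- synthetic_bone_spec("femur", mesh_density = 2.5, seed = 19)
  g1 <- generate_bone(spec)
  g2 <- generate_bone(spec)
  expect_identical(g1$model$mesh$vertices, g2$model$mesh$vertices)
  expect_identical(g1$model$mesh$faces, g2$model$mesh$faces)
  expect_identical(g1$landmarks, g2$landmarks)

  left <- generate_bone(synthetic_bone_spec("femur", side = "left",
                                            mesh_density = 2.5, seed = 19))
  expect_equal(left$landmarks[, 1L], -g1$landmarks[, 1L])
  expect_equal(left$landmarks[, 2:3], g1$landmarks[, 2:3])
  expect_equal(mesh_volume(left$model$mesh), mesh_volume(g1$model$mesh),
               tolerance = 1e-9)

  expect_error(synthetic_bone_spec("femur", mesh_density = 5), "too coarse")
})

test_that("perturbation honors its spec exactly", {
  gen <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2,
                                           seed = 20))
  none <- perturb_bone(gen$model, perturbation_spec(offset_rms = 0, seed = 1))
  expect_equal(none$mesh$vertices, gen$model$mesh$vertices)
  expect_identical(none$mesh$faces, gen$model$mesh$faces)
  expect_equal(none$source, "prediction")

  p <- perturbation_spec(offset_rms = 0.9, seed = 5)
  pred <- perturb_bone(gen$model, p)
  offs <- attr(pred, "true_offset")
  expect_equal(sqrt(mean(offs^2)), 0.9, tolerance = 1e-12)
  # reproducible
  pred2 <- perturb_bone(gen$model, p)
  expect_equal(pred$mesh$vertices, pred2$mesh$vertices, tolerance = 1e-12)

  expect_error(perturb_bone(gen$model,
                            perturbation_spec(offset_rms = 0.5,
                                              offset_correlation_length = 1,
                                              seed = 1)),
               "twice the mesh edge")
  expect_error(perturb_bone(pred, p), "ground-truth")
})

test_that("pure rigid misalignment is fully removed by registration", {
  gen <- generate_bone(synthetic_bone_spec("tibia", mesh_density = 2,
                                           seed = 21))
  rigid <- rigid_transform(rotation_about_axis(c(0.3, 1, 0.2), 6),
                           c(4, -2, 3))
  pred <- perturb_bone(gen$model, perturbation_spec(rigid = rigid,
                                                    offset_rms = 0, seed = 1))
  g <- global_rmse(pred, gen$model, register = TRUE, keep_distances = FALSE)
  expect_lt(g$rmse, 0.05)
})

test_that("simulated annotations respect the study-design counts", {
  genf <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2.5,
                                            seed = 22))
  gent <- generate_bone(synthetic_bone_spec("tibia", mesh_density = 2,
                                            seed = 23))
  noise <- annotation_noise_spec(seed = 9)
  annf <- simulate_annotations(genf$landmarks, genf$model$mesh, noise,
                               "ground_truth", bone = "femur")
  annt <- simulate_annotations(gent$landmarks, gent$model$mesh, noise,
                               "ground_truth", bone = "tibia")
  # 5 femoral regions x 6 = 30 plus 2 epicondyles x 6; tibia 3 x 6 = 18
  region_f <- annf[annf$landmark %in% landmark_names("femur", "region"), ]
  expect_equal(nrow(region_f), 30L)
  expect_equal(nrow(annt), 18L)
  counts <- table(annf$landmark)
  expect_true(all(counts == 6L))

  zero <- simulate_annotations(genf$landmarks, genf$model$mesh,
                               annotation_noise_spec(observer_bias_sd = 0,
                                                     repeat_sd = 0, seed = 1),
                               "ground_truth", bone = "femur")
  for (lm in rownames(genf$landmarks)) {
    pts <- as.matrix(zero[zero$landmark == lm, c("x", "y", "z")])
    expect_equal(max(dist(pts)), 0)  # all six coincide (same snapped vertex)
    expect_lt(sqrt(sum((pts[1L, ] - genf$landmarks[lm, ])^2)), 2.5)
  }
})

test_that("annotation angle statistics match a Monte-Carlo oracle", {
  # TEA baseline measured through the full pipeline (simulate_annotations ->
  # build_annotated_axes -> project_axis -> baseline_stats) against a
  # large-sample Monte-Carlo oracle that replays the identical noise model
  # (Gaussian endpoint noise + nearest-vertex snap) with direct arithmetic
  gen <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2,
                                           seed = 24, size_jitter = 0))
  mesh <- gen$model$mesh
  plane <- make_plane(c(0, 0, 25), c(0, 0, 1))
  noise_sd <- 1
  means <- vapply(1:120, function(s) {
    ann <- simulate_annotations(gen$landmarks, mesh,
                                annotation_noise_spec(observer_bias_sd = 0,
                                                      repeat_sd = noise_sd,
                                                      seed = 1000 + s),
                                "ground_truth", bone = "femur")
    axes <- lapply(build_annotated_axes(ann, "TEA", "ground_truth"),
                   project_axis, plane = plane)
    baseline_stats(axes)$mean_deg
  }, numeric(1))

  lm <- gen$landmarks
  set.seed(99)
  n_mc <- 1e5
  snap <- function(truth) {
    pts <- matrix(rep(truth, each = n_mc), n_mc, 3L) +
      matrix(rnorm(3L * n_mc, sd = noise_sd), n_mc, 3L)
    mesh$vertices[RANN::nn2(mesh$vertices, pts, k = 1L)$nn.idx[, 1L], ,
                  drop = FALSE]
  }
  lat <- snap(lm["lateral_epicondyle", ])
  med <- snap(lm["medial_epicondyle", ])
  d <- lat - med  # plane normal is +z: in-plane angle from (dx, dy)
  theta <- atan2(d[, 2L], d[, 1L])
  pair_angle <- abs(theta - theta[sample.int(n_mc)])
  pair_angle <- pmin(pair_angle, pi - pair_angle) * 180 / pi
  oracle <- mean(pair_angle)
  expect_equal(mean(means), oracle, tolerance = 0.05)
})

test_that("cohort fixtures are self-consistent and reproducible", {
  dir1 <- file.path(tempdir(), "cohortA")
  unlink(dir1, recursive = TRUE)
  man1 <- suppressMessages(make_cohort(dir1, n_patients = 2L, seed = 31,
                                       mesh_density = 2,
                                       voxel_spacing = 1.5))
  expect_length(man1$patients, 2L)
  expect_true(all(c("femur_gt.stl", "femur_pred.stl", "tibia_gt.stl",
                    "tibia_pred.stl", "femur_gt.nii.gz", "annotations.json")
                  %in% list.files(file.path(dir1, "P001"))))
  rms_values <- vapply(man1$patients, function(p)
    p$bones$femur$offset_rms, numeric(1))
  expect_true(all(rms_values >= 0.3))

  # everything written parses back through the production readers
  mesh <- suppressMessages(read_stl(file.path(dir1, "P001",
                                              "femur_pred.stl")))
  expect_gt(nrow(mesh$vertices), 100L)
  mask <- suppressMessages(load_mask(file.path(dir1, "P001",
                                               "femur_gt.nii.gz")))
  expect_gt(mask_foreground_count(mask), 0L)
  ann <- read_annotations_json(file.path(dir1, "P001", "annotations.json"))
  expect_s3_class(ann, "landmark_annotations")
  expect_setequal(unique(ann$model_source), c("ground_truth", "prediction"))

  # regenerating under the same master seed reproduces the manifest
  dir2 <- file.path(tempdir(), "cohortB")
  unlink(dir2, recursive = TRUE)
  man2 <- suppressMessages(make_cohort(dir2, n_patients = 2L, seed = 31,
                                       mesh_density = 2,
                                       voxel_spacing = 1.5))
  expect_identical(man1$patients, man2$patients)

  expect_error(suppressMessages(make_cohort(dir1, n_patients = 1L)),
               "not empty")
})

test_that("voxelize-then-mesh round trip stays under one voxel of error", {
  gen <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2,
                                           seed = 25))
  mask <- voxelize_mesh(gen$model$mesh, spacing = 0.8)
  suppressMessages(remesh <- mask_to_mesh(mask))
  pred <- bone_model(remesh, "femur", "right", "prediction", "synthetic",
                     mirror_left = FALSE)
  g <- global_rmse(pred, gen$model, register = TRUE, keep_distances = FALSE)
  expect_lt(g$rmse, 0.8)
})
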