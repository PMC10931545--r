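make_endpoint_rows <- function(landmarks, points, model_source = "ground_truth",
                               observer = "a", rep_idx = 1L, bone = "femur") {
  landmark_annotations(data.frame(
    patient_id = "p1", bone = bone, side = "right",
    model_source = model_source, landmark = landmarks,
    observer_id = observer, repeat_index = rep_idx,
    x = points[, 1L], y = points[, 2L], z = points[, 3L]))
}

test_that("build_axis3d infers the axis and enforces pairing rules", {
  rows <- make_endpoint_rows(c("lateral_epicondyle", "medial_epicondyle"),
                             rbind(c(0, 0, 0), c(80, 0, 0)))
  ax <- build_axis3d(rows[1L, ], rows[2L, ])
  expect_equal(ax$name, "TEA")
  expect_equal(ax$direction, c(1, 0, 0))
  expect_equal(sqrt(sum((ax$p1 - ax$p0)^2)), 80)

  # swapped order describes the same undirected line
  ax2 <- build_axis3d(rows[2L, ], rows[1L, ])
  expect_equal(abs(sum(ax$direction * ax2$direction)), 1)

  pca_rows <- make_endpoint_rows(
    c("posterior_lateral_condyle", "posterior_medial_condyle"),
    rbind(c(20, -20, 15), c(-20, -20, 15)))
  expect_equal(build_axis3d(pca_rows[1L, ], pca_rows[2L, ])$name, "PCA")

  bad <- make_endpoint_rows(c("lateral_epicondyle", "posterior_medial_condyle"),
                            rbind(c(0, 0, 0), c(80, 0, 0)))
  expect_error(build_axis3d(bad[1L, ], bad[2L, ]), "pair")
  mixed <- rows
  mixed$observer_id <- c("a", "b")
  mixed <- landmark_annotations(mixed)
  expect_error(build_axis3d(mixed[1L, ], mixed[2L, ]), "share")
})

test_that("a complete annotation set yields 6 axes per bone model", {
  gen <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2.5,
                                           seed = 15))
  ann <- simulate_annotations(gen$landmarks, gen$model$mesh,
                              annotation_noise_spec(seed = 3),
                              "ground_truth", bone = "femur")
  tea <- build_annotated_axes(ann, "TEA", "ground_truth")
  pca <- build_annotated_axes(ann, "PCA", "ground_truth")
  expect_length(tea, 6L)
  expect_length(pca, 6L)
})

test_that("axis projection preserves in-plane angles and rejects degeneracy", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  prov <- list(model_source = "ground_truth", observer_id = "a",
               repeat_index = 1L)
  mk_inplane <- function(angle_rad, obs) {
    axis3d("TEA", c(0, 0, 0), c(cos(angle_rad), sin(angle_rad), 0) * 50,
           provenance = list(model_source = "ground_truth",
                             observer_id = obs, repeat_index = 1L))
  }
  a1 <- project_axis(mk_inplane(0.3, "a"), plane)
  a2 <- project_axis(mk_inplane(0.3 + 0.25, "b"), plane)
  expect_equal(angle_between(a1, a2), 0.25 * 180 / pi, tolerance = 1e-9)

  tilted <- axis3d("TEA", c(1, 2, 3), c(41, 2, 23), provenance = prov)
  p2 <- project_axis(tilted, plane)
  expect_equal(p2$point,
               as.numeric(project_to_plane(tilted$p0, plane)))

  vertical <- axis3d("TEA", c(0, 0, 0), c(0, 0, 50), provenance = prov)
  expect_error(project_axis(vertical, plane), "degenerate")
})

test_that("angle_between is symmetric, flip-invariant and in [0, 90]", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  a <- make_axis2d(0, "ground_truth", "a", 1L, plane)
  b <- make_axis2d(90, "ground_truth", "b", 1L, plane)
  expect_equal(angle_between(a, a), 0)
  expect_equal(angle_between(a, b), 90)
  expect_equal(angle_between(a, b), angle_between(b, a))

  # antiparallel with a 5-degree offset: (1, 0) vs (-1, tan 5) scaled
  th <- 5 * pi / 180
  flipped <- make_axis2d(180 + 5, "ground_truth", "c", 1L, plane)
  expect_equal(angle_between(a, flipped), 5, tolerance = 1e-9)
})

test_that("baseline stats enumerate C(n,2) pairs and match brute force exactly", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  og <- obs_grid()
  angles_deg <- c(0, 1, 2, 3, 4, 5)
  ct <- lapply(seq_len(6L), function(i)
    make_axis2d(angles_deg[i], "ground_truth", og$observer_id[i],
                og$repeat_index[i], plane))
  bs <- baseline_stats(ct)
  expect_equal(bs$n_pairs, 15L)
  oracle <- abs(outer(angles_deg, angles_deg, `-`))
  oracle <- oracle[upper.tri(oracle)]
  expect_equal(bs$mean_deg, mean(oracle), tolerance = 1e-12)
  expect_equal(bs$sd_deg, sd(oracle), tolerance = 1e-12)

  same <- lapply(seq_len(6L), function(i)
    make_axis2d(10, "ground_truth", og$observer_id[i], og$repeat_index[i],
                plane))
  bs0 <- baseline_stats(same)
  expect_equal(bs0$mean_deg, 0)
  expect_equal(bs0$sd_deg, 0)
  expect_equal(bs0$n_pairs, 15L)

  dup <- ct
  dup[[2L]] <- make_axis2d(1, "ground_truth", "a", 1L, plane)
  expect_error(baseline_stats(dup), "duplicate")
})

test_that("cross stats enumerate n*m pairs; pure rotation gives mean=phi, sd=0", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  og <- obs_grid()
  ct <- lapply(seq_len(6L), function(i)
    make_axis2d(10, "ground_truth", og$observer_id[i], og$repeat_index[i],
                plane))
  xr <- lapply(seq_len(6L), function(i)
    make_axis2d(10 + 3.5, "prediction", og$observer_id[i],
                og$repeat_index[i], plane))
  cs <- cross_stats(ct, xr)
  expect_equal(cs$n_pairs, 36L)
  expect_equal(cs$mean_deg, 3.5, tolerance = 1e-9)
  expect_equal(cs$sd_deg, 0, tolerance = 1e-9)

  # brute-force double loop equals the implementation exactly
  set.seed(21)
  angles_ct <- runif(6, 0, 20)
  angles_xr <- runif(6, 0, 20)
  ct2 <- lapply(seq_len(6L), function(i)
    make_axis2d(angles_ct[i], "ground_truth", og$observer_id[i],
                og$repeat_index[i], plane))
  xr2 <- lapply(seq_len(6L), function(i)
    make_axis2d(angles_xr[i], "prediction", og$observer_id[i],
                og$repeat_index[i], plane))
  cs2 <- cross_stats(ct2, xr2)
  brute <- as.vector(vapply(ct2, function(b) vapply(xr2, function(a)
    angle_between(a, b), numeric(1)), numeric(6)))
  expect_equal(cs2$mean_deg, mean(brute), tolerance = 1e-12)
  expect_equal(cs2$sd_deg, sd(brute), tolerance = 1e-12)
  expect_error(cross_stats(ct2, ct2), "model source|expected all")
})

test_that("baseline mean grows monotonically with endpoint noise", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  og <- obs_grid()
  mean_at_noise <- function(sd_mm, seed) {
    set.seed(seed)
    means <- replicate(8L, {
      axes <- lapply(seq_len(6L), function(i) {
        p0 <- c(-40, 0, 0) + rnorm(3L, sd = sd_mm)
        p1 <- c(40, 0, 0) + rnorm(3L, sd = sd_mm)
        project_axis(axis3d("TEA", p0, p1, provenance = list(
          model_source = "ground_truth", observer_id = og$observer_id[i],
          repeat_index = og$repeat_index[i])), plane)
      })
      baseline_stats(axes)$mean_deg
    })
    mean(means)
  }
  m <- vapply(c(0.3, 1, 3), mean_at_noise, numeric(1), seed = 33)
  expect_true(all(diff(m) > 0))
})

test_that("study report pools angles and exposes a systematic rotation", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  og <- obs_grid()
  sim_bone <- function(seed, systematic_deg) {
    set.seed(seed)
    noisy_axis <- function(src, i, extra) {
      th <- rnorm(1L, sd = 0.1)
      make_axis2d(extra + th, src, og$observer_id[i], og$repeat_index[i],
                  plane)
    }
    ct <- lapply(seq_len(6L), function(i) noisy_axis("ground_truth", i, 0))
    xr <- lapply(seq_len(6L), function(i)
      noisy_axis("prediction", i, systematic_deg))
    list(baseline = baseline_stats(ct), cross = cross_stats(ct, xr))
  }

  # zero reconstruction error: cross mean tracks the baseline mean
  stats0 <- unlist(lapply(1:20, function(s) sim_bone(s, 0)),
                   recursive = FALSE)
  rep0 <- study_axis_report(stats0)
  expect_equal(rep0$cross_mean, rep0$baseline_mean, tolerance = 0.05)

  # a systematic 2-degree rotation raises the cross mean by about 2 degrees
  stats2 <- unlist(lapply(1:20, function(s) sim_bone(100 + s, 2)),
                   recursive = FALSE)
  rep2 <- study_axis_report(stats2)
  expect_equal(rep2$cross_mean - rep2$baseline_mean, 2, tolerance = 0.15)
  expect_equal(rep2$n_baseline_pairs, 20 * 15)
  expect_equal(rep2$n_cross_pairs, 20 * 36)

  # single bone: report equals that bone's stats
  one <- sim_bone(7, 1)
  rep1 <- study_axis_report(list(one$baseline, one$cross))
  expect_equal(rep1$baseline_mean, one$baseline$mean_deg)
  expect_equal(rep1$cross_mean, one$cross$mean_deg)
})
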