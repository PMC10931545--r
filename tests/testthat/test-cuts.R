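test_that("anatomical axis fitting recovers cylinder axes", {
  cyl <- mesh_cylinder(radius = 12, height = 150, n_seg = 96, n_rings = 50)
  ax <- fit_anatomical_axis(cyl)
  expect_lt(acos(min(1, abs(ax$direction[3L]))) * 180 / pi, 0.1)

  tilted <- mesh_cylinder(radius = 12, height = 150, n_seg = 96,
                          n_rings = 50, axis_tilt_deg = 7)
  true_dir <- as.numeric(rotation_about_axis(c(1, 0, 0), 7) %*% c(0, 0, 1))
  ax7 <- fit_anatomical_axis(tilted)
  ang <- acos(min(1, abs(sum(ax7$direction * true_dir)))) * 180 / pi
  expect_lt(ang, 0.2)
})

test_that("a condylar bulge outside the shaft range leaves the axis unchanged", {
  shaft <- mesh_cylinder(radius = 12, height = 150, n_seg = 96, n_rings = 50)
  bulge <- mesh_sphere(radius = 20, n_lat = 16, n_lon = 32,
                       center = c(10, -8, -70))  # near the distal end
  combined <- triangle_mesh(rbind(shaft$vertices, bulge$vertices),
                            rbind(shaft$faces,
                                  bulge$faces + nrow(shaft$vertices)))
  ax <- fit_anatomical_axis(combined, shaft_fraction_range = c(0.35, 0.8))
  expect_lt(acos(min(1, abs(ax$direction[3L]))) * 180 / pi, 0.2)
})

test_that("too-short shafts are rejected", {
  stub <- mesh_cylinder(radius = 1.5, height = 7, n_seg = 48, n_rings = 6)
  expect_error(fit_anatomical_axis(stub), "5 usable")
})

test_that("mechanical axis rotation is exact, side-aware and bounded", {
  anat <- axis3d("anatomical", c(0, 0, 0), c(2, 5, 120))
  expect_equal(estimate_mechanical_axis(anat, 0)$direction, anat$direction)
  mech <- estimate_mechanical_axis(anat, 5, "right")
  ang <- acos(abs(sum(anat$direction * mech$direction))) * 180 / pi
  expect_equal(ang, 5, tolerance = 1e-6)
  expect_lt(mech$p1[1L], anat$p1[1L])  # proximal end moves medially (-x)

  mech_l <- estimate_mechanical_axis(anat, 5, "left")
  ang_l <- acos(abs(sum(anat$direction * mech_l$direction))) * 180 / pi
  expect_equal(ang_l, 5, tolerance = 1e-6)
  expect_gt(mech_l$p1[1L], anat$p1[1L])  # mirrored sign, same magnitude

  expect_error(estimate_mechanical_axis(anat, 20), "within")
})

test_that("femoral cut plane sits exactly offset from the distal medial condyle", {
  gen <- generate_bone(synthetic_bone_spec("femur", mesh_density = 2,
                                           seed = 13))
  mesh <- gen$model$mesh
  anat <- fit_anatomical_axis(mesh)
  mech <- estimate_mechanical_axis(anat, 5, "right")
  plane <- femoral_cut_plane(mech, mesh, offset = 9, side = "right")
  ref <- attr(plane, "reference_vertex")
  v <- mesh$vertices[ref, ]
  expect_equal(abs(plane_signed_distance(v, plane)), 9, tolerance = 1e-12)
  # the reference vertex is medial (x below the mid-plane) and distal
  bb <- mesh_bbox(mesh)
  expect_lt(v[1L], (bb[1L, 1L] + bb[2L, 1L]) / 2)
  expect_lt(v[3L], bb[1L, 3L] + 0.25 * (bb[2L, 3L] - bb[1L, 3L]))

  # offset 0 passes through the vertex; doubling doubles the distance
  p0 <- femoral_cut_plane(mech, mesh, offset = 0)
  expect_equal(plane_signed_distance(v, p0), 0, tolerance = 1e-12)
  p18 <- femoral_cut_plane(mech, mesh, offset = 18)
  expect_equal(abs(plane_signed_distance(v, p18)), 18, tolerance = 1e-12)

  sideways <- axis3d("mechanical", c(0, 0, 20), c(100, 0, 30))
  expect_error(femoral_cut_plane(sideways, mesh), "implausible axis")
})

test_that("tibial cut plane honors slope, offset and plateau centring", {
  gen <- generate_bone(synthetic_bone_spec("tibia", mesh_density = 2,
                                           seed = 14))
  mesh <- gen$model$mesh
  anat <- fit_anatomical_axis(mesh)

  p0 <- tibial_cut_plane(anat, mesh, slope = 0, offset = 9)
  d <- anat$direction * sign(anat$direction[3L])
  expect_equal(abs(sum(p0$normal * d)), 1, tolerance = 1e-9)
  center <- attr(p0, "plateau_center")
  expect_equal(plane_signed_distance(center, p0), 9, tolerance = 1e-9)
  expect_lt(sqrt(sum(project_to_plane(center, p0)^2)), 1e-9)

  p3 <- tibial_cut_plane(anat, mesh, slope = 3, offset = 9)
  ang <- acos(min(1, abs(sum(p3$normal * d)))) * 180 / pi
  expect_equal(ang, 3, tolerance = 1e-6)
  expect_lt(p3$normal[2L], d[2L])  # normal tips posteriorly

  expect_error(tibial_cut_plane(anat, mesh, slope = 15), "within")
})

test_that("cylinder cross-section matches the closed form after resampling", {
  cyl <- mesh_cylinder(radius = 10, height = 100, n_seg = 600, n_rings = 30)
  plane <- make_plane(c(0, 0, 10), c(0, 0, 1))
  loops <- extract_cut_contour(cyl, plane, spacing = 0.1)
  expect_length(loops, 1L)
  l1 <- loops[[1L]]
  expect_lte(abs(nrow(l1$points) - round(2 * pi * 10 / 0.1)), 1L)
  expect_equal(abs(contour_area(l1)), pi * 100, tolerance = 0.005)
  # consecutive resampled spacing is uniform within 10% of nominal
  p <- rbind(l1$points, l1$points[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  expect_true(all(abs(seg - 0.1) < 0.01))
})

test_that("cube section parallel to a face is the square outline", {
  edge <- 20
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge),
                             z = c(0, edge)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),  # z faces
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),  # y faces
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))  # x faces
  cube <- triangle_mesh(v, f)
  plane <- make_plane(c(0, 0, edge / 2), c(0, 0, 1))
  loops <- extract_cut_contour(cube, plane, spacing = 0.1)
  expect_length(loops, 1L)
  p <- rbind(loops[[1L]]$points, loops[[1L]]$points[1L, ])
  perim <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(perim, 4 * edge, tolerance = 0.005)
  expect_equal(abs(contour_area(loops[[1L]])), edge^2, tolerance = 0.005)
})

test_that("planes that miss or graze the mesh are rejected", {
  cyl <- mesh_cylinder(radius = 10, height = 100)
  expect_error(extract_cut_contour(cyl, make_plane(c(0, 0, 80), c(0, 0, 1))),
               "misses")
  sph <- mesh_sphere(radius = 10, n_lat = 30, n_lon = 60)
  tangent <- make_plane(c(0, 0, 10), c(0, 0, 1))
  expect_error(extract_cut_contour(sph, tangent, spacing = 0.1),
               "misses|degenerate")
})

test_that("contour RMSE: identity, concentric circles, rigid invariance, oracle", {
  plane <- make_plane(c(0, 0, 0), c(0, 0, 1))
  circle <- function(r, n = round(2 * pi * r / 0.1), center = c(0, 0)) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    contour2d(cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)),
              spacing = 2 * pi * r / n, plane = plane)
  }
  c10 <- circle(10)
  expect_equal(contour_rmse(c10, c10)$rmse, 0)
  expect_equal(contour_rmse(c10, circle(10.6))$rmse, 0.6, tolerance = 0.01)

  # invariance under a common in-plane rigid motion
  rot <- function(ct, th, shift) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    contour2d(sweep(ct$points %*% t(R), 2L, shift, `+`), ct$spacing, plane)
  }
  a <- circle(8)
  b <- circle(8.5, center = c(1, -0.5))
  r0 <- contour_rmse(a, b)$rmse
  r1 <- contour_rmse(rot(a, 0.7, c(3, 4)), rot(b, 0.7, c(3, 4)))$rmse
  expect_equal(r0, r1, tolerance = 1e-9)

  # kd route equals the brute-force oracle exactly on 100-point contours
  small_a <- circle(5, n = 100)
  small_b <- circle(5.4, n = 97)
  expect_identical(contour_rmse(small_a, small_b, method = "kd")$rmse,
                   contour_rmse(small_a, small_b, method = "brute")$rmse)

  other <- make_plane(c(0, 0, 1), c(0, 0, 1))
  bad <- contour2d(c10$points, c10$spacing, other)
  expect_error(contour_rmse(c10, bad), "frame mismatch")
})

test_that("uniform normal offset shows up in the cut-contour RMSE within 15%", {
  cyl <- mesh_cylinder(radius = 15, height = 80, n_seg = 400, n_rings = 20)
  offset <- triangle_mesh(cbind(cyl$vertices[, 1:2] * (15.5 / 15),
                                cyl$vertices[, 3L]), cyl$faces)
  plane <- make_plane(c(0, 0, 5), c(0, 0, 1))
  gt_loop <- extract_cut_contour(cyl, plane, 0.1)[[1L]]
  pred_loop <- extract_cut_contour(offset, plane, 0.1)[[1L]]
  expect_equal(contour_rmse(pred_loop, gt_loop)$rmse, 0.5, tolerance = 0.15)
})

test_that("multiple loops come back sorted by enclosed area", {
  a <- mesh_cylinder(radius = 12, height = 60, center = c(-25, 0, 0))
  b <- mesh_cylinder(radius = 6, height = 60, center = c(20, 0, 0))
  two <- triangle_mesh(rbind(a$vertices, b$vertices),
                       rbind(a$faces, b$faces + nrow(a$vertices)))
  loops <- extract_cut_contour(two, make_plane(c(0, 0, 0), c(0, 0, 1)), 0.2)
  expect_length(loops, 2L)
  areas <- vapply(loops, function(l) abs(contour_area(l)), numeric(1))
  expect_true(areas[1L] > areas[2L])
  expect_equal(areas, pi * c(144, 36), tolerance = 0.01)
})
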