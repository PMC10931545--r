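# analytic fixture meshes and masks, built in code at test time

# closed cylinder along +z, centred at `center`, optional tilt about +x
mesh_cylinder <- function(radius = 10, height = 100, n_seg = 128,
                          n_rings = 40, center = c(0, 0, 0),
                          axis_tilt_deg = 0) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  zs <- seq(-height / 2, height / 2, length.out = n_rings)
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(th), radius * sin(th), z)))
  v <- rbind(v, c(0, 0, -height / 2), c(0, 0, height / 2))
  nb <- nrow(v) - 1L
  nt <- nrow(v)
  f <- matrix(0L, 0L, 3L)
  for (r in seq_len(n_rings - 1L)) {
    i0 <- (r - 1L) * n_seg
    a <- i0 + seq_len(n_seg)
    b <- i0 + c(seq_len(n_seg - 1L) + 1L, 1L)
    f <- rbind(f, cbind(a, b, a + n_seg), cbind(b, b + n_seg, a + n_seg))
  }
  a <- seq_len(n_seg)
  b <- c(seq_len(n_seg - 1L) + 1L, 1L)
  top0 <- (n_rings - 1L) * n_seg
  f <- rbind(f, cbind(b, a, nb), cbind(top0 + a, top0 + b, nt))
  m <- triangle_mesh(v, f)
  if (axis_tilt_deg != 0)
    m <- transform_mesh(m, rigid_transform(
      rotation_about_axis(c(1, 0, 0), axis_tilt_deg)))
  triangle_mesh(sweep(m$vertices, 2L, center, `+`), m$faces)
}

# unit-style tetrahedron with integer (float32-exact) coordinates
mesh_tetrahedron <- function(scale = 10) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L), c(2L, 3L, 4L))
  triangle_mesh(v, f)
}

# triangulated icosphere-free sphere: lat/long parameterization
mesh_sphere <- function(radius = 10, n_lat = 24, n_lon = 48,
                        center = c(0, 0, 0)) {
  lat <- seq(0, pi, length.out = n_lat + 2L)[-c(1L, n_lat + 2L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  v <- do.call(rbind, lapply(lat, function(ph)
    cbind(radius * sin(ph) * cos(lon), radius * sin(ph) * sin(lon),
          radius * cos(ph))))
  v <- rbind(v, c(0, 0, radius), c(0, 0, -radius))
  north <- nrow(v) - 1L
  south <- nrow(v)
  f <- matrix(0L, 0L, 3L)
  for (r in seq_len(n_lat - 1L)) {
    i0 <- (r - 1L) * n_lon
    a <- i0 + seq_len(n_lon)
    b <- i0 + c(seq_len(n_lon - 1L) + 1L, 1L)
    f <- rbind(f, cbind(a, a + n_lon, b), cbind(b, a + n_lon, b + n_lon))
  }
  a <- seq_len(n_lon)
  b <- c(seq_len(n_lon - 1L) + 1L, 1L)
  bot0 <- (n_lat - 1L) * n_lon
  f <- rbind(f, cbind(a, b, north), cbind(bot0 + b, bot0 + a, south))
  triangle_mesh(sweep(v, 2L, center, `+`), f)
}

# solid-sphere binary mask centred in its grid
sphere_mask <- function(radius_mm = 10, spacing = 0.5, margin_vox = 5L) {
  n <- as.integer(ceiling(2 * radius_mm / spacing)) + 2L * margin_vox
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  r2 <- outer(ax^2, ax^2, `+`)
  grid <- array(rep(r2, times = n) + rep(ax^2, each = n * n),
                dim = c(n, n, n)) <= radius_mm^2
  volumetric_mask(grid, spacing = rep(spacing, 3L),
                  origin = rep(ax[1L], 3L))
}

# solid axis-aligned cube mask
cube_mask <- function(edge_vox = 20L, spacing = 1, margin_vox = 3L) {
  n <- edge_vox + 2L * margin_vox
  grid <- array(FALSE, dim = c(n, n, n))
  idx <- margin_vox + seq_len(edge_vox)
  grid[idx, idx, idx] <- TRUE
  volumetric_mask(grid, spacing = rep(spacing, 3L), origin = c(0, 0, 0))
}

# canonical form for comparing meshes up to vertex re-indexing
canon_mesh <- function(m) {
  o <- order(m$vertices[, 1L], m$vertices[, 2L], m$vertices[, 3L])
  v <- m$vertices[o, , drop = FALSE]
  map <- integer(nrow(v))
  map[o] <- seq_len(nrow(v))
  f <- matrix(map[m$faces], ncol = 3L)
  f <- t(apply(f, 1L, function(r) {
    i <- which.min(r)
    r[c(i:3L, seq_len(i - 1L))]
  }))
  f <- f[order(f[, 1L], f[, 2L], f[, 3L]), , drop = FALSE]
  list(vertices = v, faces = f)
}

# minimal valid annotation rows around given points
make_annotation_df <- function(pts, landmark = "anterior_cortex",
                               bone = "femur", model_source = "prediction",
                               patient_id = "p1", side = "right") {
  n <- nrow(pts)
  landmark_annotations(data.frame(
    patient_id = patient_id, bone = bone, side = side,
    model_source = model_source, landmark = landmark,
    observer_id = sprintf("obs%02d", ceiling(seq_len(n) / 2)),
    repeat_index = rep_len(1:2, n),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]))
}

# 2D axis fixture at a given in-plane angle (degrees) on a shared plane
make_axis2d <- function(angle_deg, model_source, observer_id, repeat_index,
                        plane, name = "TEA", length_mm = 80) {
  th <- angle_deg * pi / 180
  p1 <- plane$origin + length_mm *
    (cos(th) * plane$u_axis + sin(th) * plane$v_axis)
  a3 <- axis3d(name, plane$origin, p1,
               provenance = list(model_source = model_source,
                                 observer_id = observer_id,
                                 repeat_index = repeat_index))
  project_axis(a3, plane)
}

# standard 3-observer x 2-repeat provenance grid
obs_grid <- function() {
  data.frame(observer_id = rep(c("a", "b", "c"), each = 2L),
             repeat_index = rep(1:2, 3L))
}
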