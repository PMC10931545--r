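#' 3D anatomical axis
#'
#' A named line segment in 3D with a normalized direction from `p0` to
#' `p1`. For bone axes the convention is distal at `p0`, proximal at `p1`.
#'
#' @param name one of `"anatomical"`, `"mechanical"`, `"TEA"`, `"PCA"`,
#'   `"MLTA"`.
#' @param p0,p1 length-3 endpoints (mm); must be more than 1 mm apart.
#' @param provenance optional list carried along (model source, observer,
#'   repeat).
#' @return an object of class `axis3d` with fields `name`, `p0`, `p1`,
#'   `direction`.
#' @export
axis3d <- function(name, p0, p1, provenance = NULL) {
  name <- match.arg(name, c("anatomical", "mechanical", "TEA", "PCA", "MLTA"))
  p0 <- as.numeric(p0)
  p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3L, length(p1) == 3L)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len <= 1) stop("axis endpoints closer than 1 mm")
  structure(list(name = name, p0 = p0, p1 = p1, direction = d / len,
                 provenance = provenance),
            class = "axis3d")
}

#' @export
print.axis3d <- function(x, ...) {
  cat(sprintf("axis3d %s: (%.1f, %.1f, %.1f) -> (%.1f, %.1f, %.1f)\n",
              x$name, x$p0[1], x$p0[2], x$p0[3], x$p1[1], x$p1[2], x$p1[3]))
  invisible(x)
}

#' Fit the anatomical (shaft) axis of a long bone
#'
#' The mesh is sliced perpendicular to its principal long axis at fixed
#' intervals within a fractional range of the longitudinal extent; each
#' slice's cross-section centroid is computed from the section contour and
#' a least-squares 3D line is fitted through the centroids. The direction
#' is oriented distal to proximal (positive z in the package's patient
#' frame).
#'
#' @param mesh a [triangle_mesh()] spanning a shaft segment.
#' @param shaft_fraction_range fractions of the longitudinal extent that
#'   bound the shaft slices (default `c(0.25, 0.75)`).
#' @param slice_interval distance between slices in mm (default 2).
#' @return an [axis3d()] named `"anatomical"` whose endpoints are the
#'   extreme slice positions projected onto the fitted line.
#' @export
fit_anatomical_axis <- function(mesh, shaft_fraction_range = c(0.25, 0.75),
                                slice_interval = 2) {
  stopifnot(is_triangle_mesh(mesh), length(shaft_fraction_range) == 2L,
            shaft_fraction_range[1] < shaft_fraction_range[2])
  v <- mesh$vertices
  pc <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 1L]
  if (pc[3L] < 0) pc <- -pc
  centroid <- colMeans(v)
  t_all <- as.numeric(sweep(v, 2L, centroid) %*% pc)
  lo <- min(t_all) + shaft_fraction_range[1] * diff(range(t_all))
  hi <- min(t_all) + shaft_fraction_range[2] * diff(range(t_all))
  positions <- seq(lo, hi, by = slice_interval)

  centroids <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    plane <- make_plane(centroid + positions[i] * pc, pc)
    loops <- tryCatch(
      extract_cut_contour(mesh, plane, spacing = 1),
      error = function(e) NULL)
    if (is.null(loops) || length(loops) == 0L) next
    c2 <- colMeans(loops[[1L]]$points)
    centroids[[i]] <- plane$origin + c2[1L] * plane$u_axis +
      c2[2L] * plane$v_axis
  }
  centroids <- do.call(rbind, centroids)
  if (is.null(centroids) || nrow(centroids) < 5L)
    stop("fewer than 5 usable shaft slices; cannot fit anatomical axis")

  line_dir <- eigen(stats::cov(centroids), symmetric = TRUE)$vectors[, 1L]
  if (line_dir[3L] < 0) line_dir <- -line_dir
  cc <- colMeans(centroids)
  tt <- as.numeric(sweep(centroids, 2L, cc) %*% line_dir)
  axis3d("anatomical", cc + min(tt) * line_dir, cc + max(tt) * line_dir)
}

#' Estimate the mechanical axis from the anatomical axis
#'
#' Rotates the anatomical axis in the coronal plane (about the
#' anteroposterior direction orthogonalized against the axis, through the
#' distal endpoint) so that the angle between the anatomical and the
#' estimated mechanical axis equals `angle` exactly. The rotation sign is
#' chosen so the proximal end moves medially, approximating the direction
#' of the femoral head; the medial side follows the right-knee convention
#' unless `side = "left"`.
#'
#' @param anatomical an [axis3d()].
#' @param angle rotation angle in degrees, within [0, 15] (default 5).
#' @param side `"right"` (default; also for left bones mirrored into the
#'   right-knee convention) or `"left"`.
#' @return an [axis3d()] named `"mechanical"` of the same length, sharing
#'   the distal endpoint.
#' @export
estimate_mechanical_axis <- function(anatomical, angle = 5,
                                     side = c("right", "left")) {
  stopifnot(inherits(anatomical, "axis3d"))
  side <- match.arg(side)
  if (angle < 0 || angle > 15) stop("angle must be within [0, 15] degrees")
  d <- anatomical$direction
  len <- sqrt(sum((anatomical$p1 - anatomical$p0)^2))
  if (angle == 0)
    return(axis3d("mechanical", anatomical$p0, anatomical$p1))
  ap <- c(0, 1, 0)
  rot_axis <- ap - sum(ap * d) * d
  rl <- sqrt(sum(rot_axis^2))
  if (rl < 1e-8) stop("axis is parallel to the AP direction")
  rot_axis <- rot_axis / rl
  medial_x <- if (side == "right") -1 else 1
  d_plus <- as.numeric(rotation_about_axis(rot_axis, angle) %*% d)
  d_minus <- as.numeric(rotation_about_axis(rot_axis, -angle) %*% d)
  d_new <- if ((d_plus[1L] - d[1L]) * medial_x > 0) d_plus else d_minus
  axis3d("mechanical", anatomical$p0, anatomical$p0 + len * d_new)
}

# guard shared by the two cut planes: the cutting axis must stay within 45
# degrees of the bone's longitudinal direction
check_axis_plausible <- function(direction) {
  dz <- abs(direction[3L])
  if (acos(min(1, max(-1, dz))) > pi / 4)
    stop("implausible axis: more than 45 degrees from the longitudinal direction")
}

#' Simulated distal femoral resection plane
#'
#' The plane is perpendicular to the estimated mechanical axis at a fixed
#' offset from the most distal point on the medial condyle. That point is
#' found as the lowest-z vertex within the medial half and distal quarter
#' of the femur's bounding extent; the plane origin is that vertex shifted
#' proximally by `offset` along the normal, so its signed distance to the
#' plane equals `offset` exactly.
#'
#' @param mechanical the estimated mechanical [axis3d()].
#' @param mesh the femur [triangle_mesh()].
#' @param offset resection offset in mm (default 9).
#' @param side `"right"` (default, right-knee convention) or `"left"`.
#' @return a [make_plane()] with attribute `reference_vertex` (index of the
#'   distal-medial-condyle vertex).
#' @export
femoral_cut_plane <- function(mechanical, mesh, offset = 9,
                              side = c("right", "left")) {
  stopifnot(inherits(mechanical, "axis3d"), is_triangle_mesh(mesh))
  side <- match.arg(side)
  n <- mechanical$direction
  if (n[3L] < 0) n <- -n  # normal points proximally
  check_axis_plausible(n)
  v <- mesh$vertices
  bb <- mesh_bbox(mesh)
  distal <- v[, 3L] <= bb[1L, 3L] + 0.25 * (bb[2L, 3L] - bb[1L, 3L])
  xmid <- (bb[1L, 1L] + bb[2L, 1L]) / 2
  medial <- if (side == "right") v[, 1L] <= xmid else v[, 1L] >= xmid
  cand <- which(distal & medial)
  if (length(cand) == 0L) stop("no vertices in the distal medial quadrant")
  ref <- cand[which.min(v[cand, 3L])]
  plane <- make_plane(v[ref, ] + offset * n, n)
  attr(plane, "reference_vertex") <- ref
  plane
}

#' Simulated proximal tibial resection plane
#'
#' The plane normal is the tibial anatomical axis tilted posteriorly by the
#' tibial slope about the medial-lateral direction (orthogonalized against
#' the axis, so the normal-to-axis angle equals `slope` exactly). The
#' origin is the plateau centre - the centroid of the most proximal 5 mm
#' band of vertices - shifted distally by `offset` along the normal.
#'
#' @param tibial_axis the tibial anatomical [axis3d()].
#' @param mesh the tibia [triangle_mesh()].
#' @param slope posterior slope in degrees, within [0, 10] (default 3; the
#'   value is a package default, not a study-specified one).
#' @param offset resection offset in mm (default 9).
#' @param plateau_band thickness of the proximal vertex band defining the
#'   plateau centre, mm (default 5).
#' @return a [make_plane()] with attribute `plateau_center`.
#' @export
tibial_cut_plane <- function(tibial_axis, mesh, slope = 3, offset = 9,
                             plateau_band = 5) {
  stopifnot(inherits(tibial_axis, "axis3d"), is_triangle_mesh(mesh))
  if (slope < 0 || slope > 10) stop("slope must be within [0, 10] degrees")
  d <- tibial_axis$direction
  if (d[3L] < 0) d <- -d
  check_axis_plausible(d)
  v <- mesh$vertices
  zmax <- max(v[, 3L])
  band <- v[, 3L] >= zmax - plateau_band
  center <- colMeans(v[band, , drop = FALSE])
  n <- d
  if (slope > 0) {
    ml <- c(1, 0, 0)
    rot_axis <- ml - sum(ml * d) * d
    rot_axis <- rot_axis / sqrt(sum(rot_axis^2))
    n_plus <- as.numeric(rotation_about_axis(rot_axis, slope) %*% d)
    n_minus <- as.numeric(rotation_about_axis(rot_axis, -slope) %*% d)
    n <- if (n_plus[2L] < n_minus[2L]) n_plus else n_minus  # tip posteriorly
  }
  plane <- make_plane(center - offset * n, n)
  attr(plane, "plateau_center") <- center
  plane
}

#' Closed 2D contour in cutting-plane coordinates
#'
#' @param points k x 2 matrix of (u, v) points in mm, ordered
#'   counter-clockwise; the polyline is closed logically (last point
#'   connects back to the first).
#' @param spacing realized resample step in mm.
#' @param plane the [make_plane()] frame the coordinates live in (optional
#'   but required for frame checks).
#' @return an object of class `contour2d`.
#' @export
contour2d <- function(points, spacing, plane = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L, spacing > 0)
  structure(list(points = points, spacing = spacing, plane = plane),
            class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf("contour2d: %d points at %.3g mm spacing, area %.2f mm^2\n",
              nrow(x$points), x$spacing, contour_area(x)))
  invisible(x)
}

#' Enclosed area of a closed contour
#'
#' Shoelace formula; positive for counter-clockwise orientation.
#'
#' @param contour a [contour2d()] or a k x 2 matrix.
#' @return signed area in mm^2.
#' @export
contour_area <- function(contour) {
  p <- if (inherits(contour, "contour2d")) contour$points else as.matrix(contour)
  q <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  sum(p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]) / 2
}

contour_perimeter <- function(p) {
  q <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

#' Intersect a cutting plane with a mesh and extract cut contours
#'
#' Computes the exact polygonal cross-section by triangle-plane segment
#' chaining (segment endpoints are keyed by the mesh edge they lie on, so
#' chaining is exact), projects it into plane coordinates, and resamples
#' every closed loop at uniform arc-length spacing. Loops are returned
#' sorted by descending enclosed area and oriented counter-clockwise;
#' resampling starts at the loop point with the minimal u coordinate (ties
#' broken by minimal v).
#'
#' @param mesh a [triangle_mesh()].
#' @param plane a [make_plane()] intersecting the mesh.
#' @param spacing resample step in mm (default 0.1, the contour rendering
#'   resolution).
#' @return list of [contour2d()] loops, largest area first.
#' @export
extract_cut_contour <- function(mesh, plane, spacing = 0.1) {
  stopifnot(is_triangle_mesh(mesh), inherits(plane, "cut_plane"), spacing > 0)
  s <- plane_signed_distance(mesh$vertices, plane)
  pos <- s >= 0
  f <- mesh$faces
  n_cross <- pos[f[, 1L]] + pos[f[, 2L]] + pos[f[, 3L]]
  crossing <- which(n_cross == 1L | n_cross == 2L)
  if (length(crossing) == 0L) stop("plane misses bone")

  # the two crossing edges of each crossing face, canonical vertex order
  seg_edges <- matrix(0L, length(crossing), 4L)  # (a1, b1, a2, b2)
  for (col in 1:3) {
    a <- f[crossing, col]
    b <- f[crossing, if (col == 3L) 1L else col + 1L]
    cr <- pos[a] != pos[b]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    slot <- ifelse(seg_edges[, 1L] == 0L, 1L, 3L)
    put <- which(cr)
    seg_edges[cbind(put, slot[put])] <- lo[put]
    seg_edges[cbind(put, slot[put] + 1L)] <- hi[put]
  }

  edge_point <- function(a, b) {
    sa <- s[a]
    sb <- s[b]
    w <- sa / (sa - sb)
    mesh$vertices[a, , drop = FALSE] +
      w * (mesh$vertices[b, , drop = FALSE] - mesh$vertices[a, , drop = FALSE])
  }
  p1 <- edge_point(seg_edges[, 1L], seg_edges[, 2L])
  p2 <- edge_point(seg_edges[, 3L], seg_edges[, 4L])
  key1 <- paste(seg_edges[, 1L], seg_edges[, 2L])
  key2 <- paste(seg_edges[, 3L], seg_edges[, 4L])

  # chain segments into loops: every edge key occurs in exactly two faces
  # of a closed manifold section
  incident <- split(rep(seq_along(key1), 2L), c(key1, key2))
  used <- logical(length(key1))
  loops3d <- list()
  for (start in seq_along(key1)) {
    if (used[start]) next
    used[start] <- TRUE
    loop_pts <- list(p1[start, ])
    cur_key <- key2[start]
    cur_pt <- p2[start, ]
    repeat {
      nxt <- incident[[cur_key]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      seg <- nxt[1L]
      used[seg] <- TRUE
      loop_pts[[length(loop_pts) + 1L]] <- cur_pt
      if (key1[seg] == cur_key) {
        cur_key <- key2[seg]
        cur_pt <- p2[seg, ]
      } else {
        cur_key <- key1[seg]
        cur_pt <- p1[seg, ]
      }
    }
    loops3d[[length(loops3d) + 1L]] <- do.call(rbind, loop_pts)
  }

  loops <- list()
  for (lp in loops3d) {
    if (nrow(lp) < 3L) next
    pts2 <- project_to_plane(lp, plane)
    if (contour_perimeter(pts2) < 3 * spacing) next  # degenerate sliver
    if (contour_area(pts2) < 0) pts2 <- pts2[rev(seq_len(nrow(pts2))), ]
    loops[[length(loops) + 1L]] <- resample_closed(pts2, spacing, plane)
  }
  if (length(loops) == 0L)
    stop("plane intersection is degenerate (no usable loop)")
  loops[order(vapply(loops, function(l) abs(contour_area(l)), numeric(1)),
              decreasing = TRUE)]
}

# uniform arc-length resampling of a closed CCW polyline; the start point is
# the input point with minimal u (ties: minimal v) for determinism
resample_closed <- function(pts, spacing, plane = NULL) {
  start <- which(pts[, 1L] == min(pts[, 1L]))
  if (length(start) > 1L) start <- start[which.min(pts[start, 2L])]
  pts <- rbind(pts[start:nrow(pts), , drop = FALSE],
               pts[seq_len(start - 1L), , drop = FALSE])
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  arc <- c(0, cumsum(seg))
  per <- arc[length(arc)]
  n <- max(3L, round(per / spacing))
  targets <- (seq_len(n) - 1L) * per / n
  idx <- findInterval(targets, arc, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(closed) - 1L)
  w <- (targets - arc[idx]) / pmax(seg[idx], .Machine$double.eps)
  out <- closed[idx, , drop = FALSE] +
    w * (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE])
  contour2d(out, spacing = per / n, plane = plane)
}

#' RMSE between two cut contours
#'
#' For each point of the predicted contour, the distance to the closest
#' point of the ground-truth contour; the result is the root mean square of
#' those distances (direction `pred_to_gt`).
#'
#' @param pred,gt [contour2d()] objects in the same plane frame.
#' @param method `"kd"` (default) or `"brute"` (oracle).
#' @return an [rmse_result()].
#' @export
contour_rmse <- function(pred, gt, method = c("kd", "brute")) {
  stopifnot(inherits(pred, "contour2d"), inherits(gt, "contour2d"))
  method <- match.arg(method)
  if (!is.null(pred$plane) && !is.null(gt$plane) &&
        !same_plane_frame(pred$plane, gt$plane))
    stop("contour frame mismatch: contours were built on different planes")
  idx <- nearest_indices(pred$points, gt$points, method)
  d <- sqrt(rowSums((pred$points - gt$points[idx, , drop = FALSE])^2))
  rmse_result(sqrt(mean(d^2)), length(d), "pred_to_gt",
              per_point_distances = d)
}

#' Export contours as a long data frame
#'
#' @param loops list of [contour2d()] (as returned by
#'   [extract_cut_contour()]).
#' @return data.frame with columns loop_id, point_index, u_mm, v_mm.
#' @export
contours_to_df <- function(loops) {
  do.call(rbind, lapply(seq_along(loops), function(i) {
    data.frame(loop_id = i, point_index = seq_len(nrow(loops[[i]]$points)),
               u_mm = loops[[i]]$points[, 1L],
               v_mm = loops[[i]]$points[, 2L])
  }))
}
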