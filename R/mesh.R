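#' Triangle surface mesh
#'
#' The universal currency of the validation pipeline: a closed triangulated
#' surface in millimetre coordinates. Vertices are stored as an n x 3 numeric
#' matrix, faces as an m x 3 integer matrix of 1-based vertex indices.
#'
#' @param vertices numeric matrix (n x 3), vertex coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices per triangle.
#' @param normals optional numeric matrix (n x 3) of per-vertex unit normals.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices must refer to existing vertices")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
              faces[, 1L] == faces[, 3L]))
      stop("degenerate face: repeated vertex index within a triangle")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    stopifnot(nrow(normals) == nrow(vertices), ncol(normals) == 3L)
  }
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Mesh bounding box
#'
#' @param mesh a [triangle_mesh()].
#' @return 2 x 3 matrix; rows are min and max, columns x/y/z (mm).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

#' Total surface area of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  e1 <- v[f[, 2L], , drop = FALSE] - a
  e2 <- v[f[, 3L], , drop = FALSE] - a
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh
#'
#' Signed tetrahedron sum (divergence theorem); the absolute value is
#' returned, so the result does not depend on face winding.
#'
#' @param mesh a closed [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  cr <- cbind(b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L],
              b[, 3L] * c3[, 1L] - b[, 1L] * c3[, 3L],
              b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  abs(sum(a * cr) / 6)
}

#' Area-weighted outward per-vertex normals
#'
#' Face normals (right-hand winding) are accumulated on their vertices and
#' normalized. If the mesh winding encloses negative signed volume the
#' normals are flipped so they point outward for closed meshes.
#'
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = f[, k], reorder = FALSE)
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  # orient outward: signed volume under current winding must be positive
  cr <- cbind(b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L],
              b[, 3L] * c3[, 1L] - b[, 1L] * c3[, 3L],
              b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  if (sum(a * cr) < 0) n <- -n
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  stopifnot(is_triangle_mesh(mesh), inherits(transform, "rigid_transform"))
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2L, transform$translation, `+`)
  triangle_mesh(v, mesh$faces)
}

#' Mirror a mesh across the x = 0 plane
#'
#' Used to bring left-side bones into the right-knee coordinate convention.
#' Face winding is flipped so the mesh orientation stays consistent.
#'
#' @param mesh a [triangle_mesh()].
#' @return the mirrored mesh.
#' @export
mirror_mesh_x <- function(mesh) {
  v <- mesh$vertices
  v[, 1L] <- -v[, 1L]
  triangle_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE])
}

#' Exact distance from points to a mesh surface
#'
#' Point-to-triangle distance, minimized over the triangles incident to the
#' `k` nearest vertices of each query point. Exact for well-shaped meshes
#' whenever the closest triangle touches one of those vertices (always true
#' for k covering the local neighbourhood).
#'
#' @param points length-3 vector or n x 3 matrix (mm).
#' @param mesh a [triangle_mesh()].
#' @param k number of nearest vertices whose incident triangles are tested
#'   (default 8).
#' @return numeric vector of distances (mm).
#' @export
point_to_mesh_distance <- function(points, mesh, k = 8L) {
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  v <- mesh$vertices
  f <- mesh$faces
  k <- min(k, nrow(v))
  nn <- RANN::nn2(v, p, k = k)$nn.idx
  incident <- split(rep(seq_len(nrow(f)), 3L), as.vector(f))
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    fids <- unique(unlist(incident[as.character(nn[i, ])], use.names = FALSE))
    if (length(fids) == 0L) {  # isolated vertices only
      out[i] <- sqrt(min(rowSums(sweep(v, 2L, p[i, ])^2)))
      next
    }
    out[i] <- min(vapply(fids, function(fi)
      point_triangle_distance(p[i, ], v[f[fi, 1L], ], v[f[fi, 2L], ],
                              v[f[fi, 3L], ]), numeric(1)))
  }
  out
}

# Euclidean distance from point p to triangle (a, b, c); clamped
# barycentric projection
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((ap - t * ab)^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((ap - t * ac)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - b - t * (c - b))^2)))
  }
  den <- va + vb + vc
  u <- vb / den
  w <- vc / den
  sqrt(sum((p - (a + u * ab + w * ac))^2))
}

#' Bone model: a mesh with immutable provenance
#'
#' Binds a surface mesh to the bone (femur/tibia), laterality, model source
#' (X-ray-based prediction vs CT-based ground truth) and patient id. Left
#' knees are mirrored into the right-knee convention on construction and the
#' mirroring is recorded.
#'
#' @param mesh a [triangle_mesh()].
#' @param bone `"femur"` or `"tibia"`.
#' @param side `"left"` or `"right"`.
#' @param source `"prediction"` or `"ground_truth"`.
#' @param patient_id character scalar.
#' @param mirror_left mirror left-side meshes into right-knee convention
#'   (default `TRUE`).
#' @return an object of class `bone_model`.
#' @export
bone_model <- function(mesh, bone, side, source, patient_id,
                       mirror_left = TRUE) {
  bone <- match.arg(bone, c("femur", "tibia"))
  side <- match.arg(side, c("right", "left"))
  source <- match.arg(source, c("prediction", "ground_truth"))
  stopifnot(is_triangle_mesh(mesh), is.character(patient_id),
            length(patient_id) == 1L)
  mirrored <- FALSE
  if (side == "left" && mirror_left) {
    mesh <- mirror_mesh_x(mesh)
    mirrored <- TRUE
  }
  structure(list(mesh = mesh, bone = bone, side = side, source = source,
                 patient_id = patient_id, mirrored = mirrored),
            class = "bone_model")
}

#' @export
print.bone_model <- function(x, ...) {
  cat(sprintf("bone_model: %s %s (%s), patient %s%s\n", x$side, x$bone,
              x$source, x$patient_id,
              if (isTRUE(x$mirrored)) " [mirrored to right convention]" else ""))
  print(x$mesh)
  invisible(x)
}
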